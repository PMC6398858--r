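#' Two-sided Mann-Whitney test p-value
#'
#' Thin wrapper around [stats::wilcox.test()] with the convention used
#' throughout the package: the exact null distribution when the combined
#' sample size is below 25 and there are no ties, the normal
#' approximation with tie correction and continuity correction
#' otherwise. No mid-p adjustment.
#'
#' @param a,b Numeric vectors (both nonempty, combined length at least 4).
#' @param exact_limit Combined sample size below which the exact
#'   distribution is used (ties permitting).
#' @return The two-sided p-value.
#' @examples
#' mann_whitney(1:4, 10:13)  # exact: 2/choose(8,4)
#' @export
mann_whitney <- function(a, b, exact_limit = 25) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be nonempty")
  if (length(a) + length(b) < 4L)
    stop("need a combined sample size of at least 4")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && (length(a) + length(b)) < exact_limit
  suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  )
}

# Fast Mann-Whitney p-values for permutation loops: the pooled values
# are ranked once, and each replicate only needs the rank sum of group A.
# Reproduces wilcox.test()'s two-sided p exactly (validated in the test
# suite): exact via pwilcox when tie-free and small, else the
# tie-corrected normal approximation with continuity correction.
.mw_prepare <- function(values, exact_limit = 25) {
  n <- length(values)
  r <- rank(values)
  nties <- table(r)
  tie_term <- sum(nties^3 - nties)
  list(r = r, n = n, tie_term = tie_term,
       exact = tie_term == 0 && n < exact_limit)
}

.mw_p <- function(prep, a_idx) {
  n1 <- length(a_idx)
  n2 <- prep$n - n1
  U <- sum(prep$r[a_idx]) - n1 * (n1 + 1) / 2
  if (prep$exact) {
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else stats::pwilcox(U, n1, n2)
    return(min(2 * p, 1))
  }
  z <- U - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) *
                ((n1 + n2 + 1) -
                 prep$tie_term / ((n1 + n2) * (n1 + n2 - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
}

#' Permute cluster labels within diagnostic strata
#'
#' Shuffles the cluster membership uniformly at random within each
#' diagnostic stratum. This is the unique permutation scheme that
#' preserves both margins exactly — every cluster keeps its size and
#' every cluster-by-diagnosis cell count is unchanged — which is what a
#' size-matched permutation null for cluster effects requires.
#'
#' @param labels Cluster labels.
#' @param strata Stratum (diagnosis) labels, aligned with `labels`.
#' @param seed Optional seed; by default the current RNG state is used.
#' @return The permuted label vector.
#' @export
permute_labels <- function(labels, strata, seed = NULL) {
  stopifnot(length(labels) == length(strata))
  if (!is.null(seed)) set.seed(seed)
  out <- labels
  for (s in unique(strata)) {
    i <- which(strata == s)
    if (length(i) > 1L) out[i] <- labels[i][sample.int(length(i))]
  }
  out
}

# Build the two comparison groups of a scheme from (possibly permuted)
# cluster labels; returns index vectors.
.comparison_groups <- function(scheme, labels, diagnosis, cluster,
                               pair = NULL, group = NULL) {
  switch(scheme,
    whole_cluster = list(a = which(labels == cluster),
                         b = which(labels != cluster)),
    diagnostic_group = list(
      a = which(labels == cluster & diagnosis == pair[1L]),
      b = which(labels == cluster & diagnosis == pair[2L])),
    diagnostic_interaction = list(
      a = which(labels == cluster & diagnosis == group),
      b = which(labels != cluster & diagnosis == group)),
    stop("unknown scheme: ", scheme)
  )
}

#' Permutation-corrected two-group comparison of a phenotype
#'
#' Tests whether cluster membership is associated with a phenotype under
#' one of three comparison schemes, and corrects the Mann-Whitney
#' p-value for unequal group sizes with a strata-preserving permutation
#' null:
#'
#' \describe{
#'   \item{`whole_cluster`}{members of the cluster vs all other
#'     subjects, ignoring diagnosis;}
#'   \item{`diagnostic_group`}{within the cluster, one diagnosis vs
#'     another (ordered pair);}
#'   \item{`diagnostic_interaction`}{subjects of one diagnosis inside
#'     the cluster vs subjects of the same diagnosis outside it — the
#'     probe for profile-by-stage interactions.}
#' }
#'
#' The observed two-sided Mann-Whitney p-value is compared with the
#' p-values obtained after `n_perm` random permutations of the cluster
#' labels within diagnostic strata (see [permute_labels()]), which keeps
#' all group sizes identical to the observed ones. The comparison is
#' declared significant when the observed p-value falls at or below the
#' `alpha` quantile of the permutation p-value distribution.
#'
#' @param phenotype Numeric vector (one value per subject).
#' @param labels Cluster labels.
#' @param diagnosis Diagnosis labels (CN/MCI/AD or any factor).
#' @param scheme One of `"whole_cluster"`, `"diagnostic_group"`,
#'   `"diagnostic_interaction"`.
#' @param cluster The cluster being tested.
#' @param pair Ordered pair of diagnoses (for `diagnostic_group`).
#' @param group Single diagnosis (for `diagnostic_interaction`).
#' @param n_perm Number of permutations.
#' @param alpha Quantile of the null used as the significance cut-off.
#' @param stratify Permute within diagnostic strata (default). With
#'   `FALSE`, labels are permuted freely (only cluster sizes preserved).
#' @param seed Optional seed.
#' @return An object of class `"permutation_test"`: list with
#'   `observed_p`, `null_ps`, `threshold` (the `alpha` quantile of
#'   `null_ps`), `significant`, group sizes `n_a`/`n_b`, `n_degenerate`
#'   (replicates with an empty or too-small group, recorded as p = 1),
#'   `scheme`, `cluster`, `n_perm`, `alpha`, `seed`.
#' @export
compare_phenotype <- function(phenotype, labels, diagnosis,
                              scheme = c("whole_cluster",
                                         "diagnostic_group",
                                         "diagnostic_interaction"),
                              cluster, pair = NULL, group = NULL,
                              n_perm = 1000, alpha = 0.05,
                              stratify = TRUE, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(phenotype) == length(labels),
            length(labels) == length(diagnosis))
  if (scheme == "diagnostic_group" && length(pair) != 2L)
    stop("'pair' must give two diagnoses for the diagnostic_group scheme")
  if (scheme == "diagnostic_interaction" && length(group) != 1L)
    stop("'group' must give one diagnosis for the diagnostic_interaction scheme")
  if (!is.null(seed)) set.seed(seed)
  g <- .comparison_groups(scheme, labels, diagnosis, cluster, pair, group)
  if (length(g$a) < 2L || length(g$b) < 2L)
    stop(sprintf(
      "group sizes %d vs %d too small for scheme %s, cluster %s",
      length(g$a), length(g$b), scheme, as.character(cluster)))
  pool_fixed <- scheme != "diagnostic_group"
  if (pool_fixed) {
    pool <- sort(c(g$a, g$b))
    prep <- .mw_prepare(phenotype[pool])
    pos <- match(seq_along(phenotype), pool)   # subject -> pool position
    pval <- function(gr) .mw_p(prep, pos[gr$a])
  } else {
    pval <- function(gr) {
      pool <- c(gr$a, gr$b)
      .mw_p(.mw_prepare(phenotype[pool]), seq_along(gr$a))
    }
  }
  observed_p <- pval(g)
  null_ps <- numeric(n_perm)
  n_degenerate <- 0L
  strata <- if (stratify) diagnosis else rep(1L, length(labels))
  for (b in seq_len(n_perm)) {
    lp <- permute_labels(labels, strata)
    gp <- .comparison_groups(scheme, lp, diagnosis, cluster, pair, group)
    if (length(gp$a) < 1L || length(gp$b) < 1L ||
        length(gp$a) + length(gp$b) < 4L) {
      null_ps[b] <- 1
      n_degenerate <- n_degenerate + 1L
    } else {
      null_ps[b] <- pval(gp)
    }
  }
  if (n_degenerate > 0L)
    warning(n_degenerate, " permutation replicate(s) had a degenerate ",
            "group; their p-values were recorded as 1")
  threshold <- unname(stats::quantile(null_ps, alpha))
  structure(list(observed_p = observed_p, null_ps = null_ps,
                 threshold = threshold,
                 significant = observed_p <= threshold,
                 n_a = length(g$a), n_b = length(g$b),
                 n_degenerate = n_degenerate, scheme = scheme,
                 cluster = cluster, pair = pair, group = group,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  lab <- switch(x$scheme,
                whole_cluster = sprintf("cluster %s vs rest", x$cluster),
                diagnostic_group = sprintf("cluster %s: %s vs %s",
                                           x$cluster, x$pair[1], x$pair[2]),
                diagnostic_interaction =
                  sprintf("%s in cluster %s vs %s elsewhere",
                          x$group, x$cluster, x$group))
  cat(sprintf("Permutation-corrected Mann-Whitney (%s)\n", lab))
  cat(sprintf("  observed p = %.4g; %.0f%% null quantile = %.4g; %s\n",
              x$observed_p, 100 * x$alpha, x$threshold,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}

#' Run all phenotype comparisons across clusters and schemes
#'
#' Iterates [compare_phenotype()] over every combination of cluster,
#' phenotype column and (scheme-dependent) diagnosis pair or group, and
#' returns one tidy row per comparison. Combinations whose observed
#' groups are too small (fewer than 2 subjects on either side) are
#' reported as skipped rows with the reason rather than dropped.
#'
#' @param phenotypes Numeric matrix (subjects x phenotypes), typically
#'   ICV-normalised volumes (see [normalize_volumes()]; the Mann-Whitney
#'   test is rank-based, so any per-subject monotone rescaling of a
#'   phenotype leaves its p-values unchanged).
#' @param labels,diagnosis Per-subject cluster and diagnosis labels.
#' @param schemes Subset of the three schemes to run.
#' @param n_perm,alpha,stratify See [compare_phenotype()].
#' @param seed Master seed; each comparison derives its own seed from it
#'   so results do not depend on iteration order.
#' @return A data frame with columns scheme, cluster, diagnosis (single,
#'   `"d1 vs d2"`, or `""`), phenotype, n_a, n_b, observed_p, null_p
#'   (the alpha null quantile), significant, n_perm, seed, status.
#' @export
interaction_analysis <- function(phenotypes, labels, diagnosis,
                                 schemes = c("whole_cluster",
                                             "diagnostic_group",
                                             "diagnostic_interaction"),
                                 n_perm = 1000, alpha = 0.05,
                                 stratify = TRUE, seed = 1L) {
  stopifnot(is.matrix(phenotypes),
            nrow(phenotypes) == length(labels))
  schemes <- match.arg(schemes, several.ok = TRUE)
  diagnosis <- as.factor(diagnosis)
  dlev <- levels(droplevels(diagnosis))
  clusters <- sort(unique(labels))
  phen_ids <- colnames(phenotypes)
  if (is.null(phen_ids)) phen_ids <- sprintf("phen_%03d", seq_len(ncol(phenotypes)))
  specs <- list()
  for (sc in schemes) for (cl in clusters) {
    if (sc == "whole_cluster") {
      specs[[length(specs) + 1L]] <- list(scheme = sc, cluster = cl,
                                          pair = NULL, group = NULL)
    } else if (sc == "diagnostic_group") {
      if (length(dlev) >= 2L) {
        cmb <- utils::combn(dlev, 2L)
        for (i in seq_len(ncol(cmb)))
          specs[[length(specs) + 1L]] <- list(scheme = sc, cluster = cl,
                                              pair = cmb[, i], group = NULL)
      }
    } else {
      for (d in dlev)
        specs[[length(specs) + 1L]] <- list(scheme = sc, cluster = cl,
                                            pair = NULL, group = d)
    }
  }
  rows <- vector("list", length(specs) * length(phen_ids))
  ri <- 0L
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    for (pi in seq_along(phen_ids)) {
      ri <- ri + 1L
      sseed <- (seed + 7919L * si + 104729L * pi) %% .Machine$integer.max
      res <- tryCatch(
        suppressWarnings(compare_phenotype(
          phenotypes[, pi], labels, diagnosis, scheme = sp$scheme,
          cluster = sp$cluster, pair = sp$pair, group = sp$group,
          n_perm = n_perm, alpha = alpha, stratify = stratify,
          seed = sseed)),
        error = function(e) conditionMessage(e))
      dlab <- if (sp$scheme == "diagnostic_group")
        paste(sp$pair, collapse = " vs ")
      else if (sp$scheme == "diagnostic_interaction") sp$group else ""
      if (is.character(res)) {
        rows[[ri]] <- data.frame(
          scheme = sp$scheme, cluster = sp$cluster, diagnosis = dlab,
          phenotype = phen_ids[pi], n_a = NA_integer_, n_b = NA_integer_,
          observed_p = NA_real_, null_p = NA_real_, significant = NA,
          n_perm = n_perm, seed = sseed,
          status = paste("skipped:", res), stringsAsFactors = FALSE)
      } else {
        rows[[ri]] <- data.frame(
          scheme = sp$scheme, cluster = sp$cluster, diagnosis = dlab,
          phenotype = phen_ids[pi], n_a = res$n_a, n_b = res$n_b,
          observed_p = res$observed_p, null_p = res$threshold,
          significant = res$significant, n_perm = n_perm, seed = sseed,
          status = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
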