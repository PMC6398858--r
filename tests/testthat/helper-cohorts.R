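# Shared fixtures: small planted cohorts and label-agreement helpers.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a small, strongly separated planted cohort that CIMLR resolves quickly
small_cohort <- function(n_clusters = 4, seed = 11, n_subjects = 80,
                         n_markers = 25, n_informative = 8,
                         marker_shift = 3, n_regions = 10, ...) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, n_markers = n_markers,
    n_informative = min(n_informative, n_markers),
    n_clusters = n_clusters,
    cluster_proportions = rep(1 / n_clusters, n_clusters),
    marker_shift = marker_shift, n_regions = n_regions,
    n_interaction_regions = min(4, n_regions %/% 2),
    seed = seed, ...))
}

# exhaustive maximum-Jaccard assignment by trying every permutation;
# the independent oracle for match_clusters()
brute_force_match <- function(ref_sets, cand_sets) {
  C <- max(length(ref_sets), length(cand_sets))
  length(ref_sets) <- C
  length(cand_sets) <- C
  ref_sets[vapply(ref_sets, is.null, TRUE)] <- list(character(0))
  cand_sets[vapply(cand_sets, is.null, TRUE)] <- list(character(0))
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  best_j <- NULL
  for (p in perms(seq_len(C))) {
    j <- vapply(seq_len(C), function(i)
      jac(ref_sets[[i]], cand_sets[[p[i]]]), numeric(1))
    if (sum(j) > best + 1e-12) {
      best <- sum(j)
      best_j <- j
    }
  }
  list(total = best, jaccard = best_j)
}

labels_to_sets <- function(labels, ids = names(labels)) {
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  lapply(sort(unique(labels)), function(l) ids[labels == l])
}
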