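#' Configuration for a synthetic blood-marker cohort
#'
#' Describes the simulated study population: cohort size, marker panel,
#' planted cluster structure, diagnosis mixture, and the brain-volume
#' phenotypes carrying diagnosis main effects and cluster-by-diagnosis
#' interaction effects. Defaults emulate a baseline Alzheimer's-disease
#' cohort of 298 subjects with 172 plasma markers, diagnosis mixture
#' 52/161/85 (CN/MCI/AD) and four latent subgroups of sizes roughly
#' 82/77/61/78.
#'
#' Markers are generated on arbitrary raw scales (random per-marker
#' location and scale), so that min-max scaling is exercised nontrivially.
#' A small informative subset of markers carries cluster-specific mean
#' shifts with a signed (+/-1) pattern per cluster, so that each cluster
#' has a distinctive high/low marker profile; signatures are drawn with a
#' minimum pairwise Hamming separation of one third of the informative
#' markers, so every pair of clusters differs on a comparable number of
#' markers. Diagnosis is sampled
#' independently of the latent cluster: the subgroups are not confounded
#' with disease stage.
#'
#' Region volumes are generated as a per-region baseline, minus a monotone
#' CN < MCI < AD atrophy effect on a fixed half of the regions, plus noise.
#' Each interaction region additionally amplifies the diagnosis effect for
#' one "driver" cluster, planting a recoverable cluster-by-diagnosis
#' interaction.
#'
#' @param n_subjects Number of subjects.
#' @param n_markers Number of blood markers.
#' @param n_informative Number of markers carrying cluster signal.
#' @param n_clusters Number of latent clusters.
#' @param cluster_proportions Probability vector over clusters (sums to 1).
#' @param marker_shift Cluster mean shift on informative markers, in units
#'   of `marker_noise_sd`.
#' @param marker_noise_sd Within-cluster marker noise SD (latent scale).
#' @param diag_proportions Probability vector over diagnoses (CN, MCI, AD).
#' @param n_regions Number of brain regions (volumes).
#' @param n_interaction_regions Number of regions with a planted
#'   cluster-by-diagnosis interaction (must not exceed the half of regions
#'   that carry a diagnosis effect).
#' @param volume_diag_effect Atrophy per diagnosis step (CN to MCI to AD),
#'   in units of the region noise SD.
#' @param volume_interaction_effect Relative amplification of the diagnosis
#'   effect in the driver cluster of an interaction region (e.g. 1.5 means
#'   the driver cluster's atrophy effect is 2.5x the baseline effect).
#' @param volume_noise_sd Region noise SD as a fraction of the region
#'   baseline volume (a coefficient of variation; default 5%).
#' @param icv_log_mean,icv_log_sd Parameters of the lognormal intracranial
#'   volume, in log mm^3.
#' @param seed Master seed; all substreams are derived from it by fixed
#'   offsets (+1 clusters, +2 diagnosis, +3 markers, +4 volumes,
#'   +5 demographics).
#'
#' @return An object of class `"cohort_config"` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 298,
                          n_markers = 172,
                          n_informative = 10,
                          n_clusters = 4,
                          cluster_proportions = c(82, 77, 61, 78) / 298,
                          marker_shift = 3,
                          marker_noise_sd = 1,
                          diag_proportions = c(52, 161, 85) / 298,
                          n_regions = 39,
                          n_interaction_regions = 4,
                          volume_diag_effect = 1,
                          volume_interaction_effect = 1.5,
                          volume_noise_sd = 0.05,
                          icv_log_mean = log(1.5e6),
                          icv_log_sd = 0.04,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_markers = as.integer(n_markers),
    n_informative = as.integer(n_informative),
    n_clusters = as.integer(n_clusters),
    cluster_proportions = as.numeric(cluster_proportions),
    marker_shift = marker_shift, marker_noise_sd = marker_noise_sd,
    diag_proportions = as.numeric(diag_proportions),
    n_regions = as.integer(n_regions),
    n_interaction_regions = as.integer(n_interaction_regions),
    volume_diag_effect = volume_diag_effect,
    volume_interaction_effect = volume_interaction_effect,
    volume_noise_sd = volume_noise_sd,
    icv_log_mean = icv_log_mean, icv_log_sd = icv_log_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_subjects", "n_markers", "n_informative", "n_clusters",
              "n_regions", "n_interaction_regions")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("'%s' must be a single positive count", f))
  }
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9)
    stop("'cluster_proportions' must sum to 1")
  if (abs(sum(cfg$diag_proportions) - 1) > 1e-9)
    stop("'diag_proportions' must sum to 1")
  if (length(cfg$cluster_proportions) != cfg$n_clusters)
    stop("'cluster_proportions' must have length n_clusters")
  if (length(cfg$diag_proportions) != 3L)
    stop("'diag_proportions' must have length 3 (CN, MCI, AD)")
  if (any(cfg$cluster_proportions < 0) || any(cfg$diag_proportions < 0))
    stop("proportions must be nonnegative")
  if (cfg$n_informative > cfg$n_markers)
    stop("'n_informative' must not exceed 'n_markers'")
  if (cfg$n_interaction_regions > cfg$n_regions %/% 2L)
    stop("'n_interaction_regions' must not exceed the number of ",
         "diagnosis-effect regions (half of 'n_regions')")
  if (cfg$marker_noise_sd <= 0 || cfg$volume_noise_sd <= 0)
    stop("noise SDs must be positive")
  # every cluster and diagnosis stratum must be populated enough for
  # downstream two-group tests to be defined
  if (min(cfg$cluster_proportions) * cfg$n_subjects < 2)
    stop("expected size of the smallest cluster is below 2; ",
         "increase 'n_subjects' or rebalance 'cluster_proportions'")
  if (min(cfg$diag_proportions) * cfg$n_subjects < 2)
    stop("expected size of the smallest diagnostic group is below 2")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d subjects, %d markers (%d informative), %d clusters\n",
              x$n_subjects, x$n_markers, x$n_informative, x$n_clusters))
  cat(sprintf("  %d regions (%d with interaction), seed %d\n",
              x$n_regions, x$n_interaction_regions, x$seed))
  invisible(x)
}

# Diagnosis-conditional demographic distributions used when simulating
# metadata (age in years, education in years, MMSE points, probabilities
# for female sex and APOE4 carriage). Values follow the published
# baseline characteristics of the emulated cohort.
.demographics <- list(
  age_mean  = c(CN = 75.1, MCI = 74.1, AD = 74.6),
  age_sd    = c(CN = 6.0,  MCI = 7.5,  AD = 7.9),
  female_p  = c(CN = 0.442, MCI = 0.335, AD = 0.47),
  educ_mean = c(CN = 15.8, MCI = 15.8, AD = 15.3),
  educ_sd   = c(CN = 2.7,  MCI = 2.9,  AD = 3.0),
  apoe4_p   = c(CN = 0.09, MCI = 0.52, AD = 0.67),
  mmse_mean = c(CN = 29.0, MCI = 26.9, AD = 23.4),
  mmse_sd   = c(CN = 1.2,  MCI = 1.8,  AD = 1.9)
)

#' Generate a synthetic cohort with planted cluster structure
#'
#' Draws a cohort according to a [cohort_config()]: a subjects-by-markers
#' matrix on arbitrary raw scales with cluster-specific mean shifts on the
#' informative markers, region volumes with diagnosis main effects and
#' cluster-by-diagnosis interactions, a lognormal intracranial volume, a
#' diagnosis label sampled independently of the latent cluster, and
#' plausible per-diagnosis demographics. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"synthetic_cohort"`: a list with elements
#'   `markers` (numeric matrix, subjects x markers), `volumes` (numeric
#'   matrix, subjects x regions, mm^3-like), `icv` (numeric vector),
#'   `diagnosis` (factor CN/MCI/AD), `true_cluster` (integer 1..C),
#'   `metadata` (data frame: subject_id, diagnosis, age, sex, education,
#'   apoe4, mmse), `informative_markers`, `effect_regions`,
#'   `interaction_regions` (with the driver cluster of each), `sign_pattern`
#'   (clusters x informative markers), and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 60, n_markers = 20,
#'                                      n_regions = 10, seed = 7))
#' table(coh$diagnosis)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n <- config$n_subjects
  m <- config$n_markers
  cl <- config$n_clusters
  subject_ids <- sprintf("S%04d", seq_len(n))
  marker_ids <- sprintf("marker_%03d", seq_len(m))
  region_ids <- sprintf("region_%02d", seq_len(config$n_regions))

  set.seed(config$seed + 1L)
  true_cluster <- sample.int(cl, n, replace = TRUE,
                             prob = config$cluster_proportions)

  set.seed(config$seed + 2L)
  diagnosis <- factor(sample(c("CN", "MCI", "AD"), n, replace = TRUE,
                             prob = config$diag_proportions),
                      levels = c("CN", "MCI", "AD"))

  set.seed(config$seed + 3L)
  informative <- sort(sample.int(m, config$n_informative))
  # signed +/-1 signature per cluster over the informative markers.
  # Signatures are redrawn until (a) every pair of clusters differs on
  # at least ceiling(n_informative/3) markers, so that all pairs of
  # subtypes have comparable profile contrast (the emulated blood
  # profiles differ broadly, not on a single marker), and (b) every
  # informative marker differs between at least two clusters — a
  # marker that shifts all clusters identically would carry no
  # between-cluster signal and would not be informative at all.
  minh <- max(1L, ceiling(config$n_informative / 3))
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    sign_pattern <- matrix(sample(c(-1, 1), cl * config$n_informative,
                                  replace = TRUE),
                           nrow = cl)
    hd <- as.matrix(stats::dist(sign_pattern, method = "manhattan")) / 2
    sep <- if (cl == 1L) Inf else min(hd[upper.tri(hd)])
    col_ok <- cl == 1L ||
      !any(apply(sign_pattern, 2, function(s) all(s == s[1L])))
    if (sep >= minh && col_ok) break
    if (attempt >= 5000L && sep >= 1 && col_ok) {
      warning("could not reach the target signature separation; ",
              "using distinct signatures with minimum Hamming ",
              "distance ", sep)
      break
    }
  }
  loc <- stats::runif(m, 0, 100)
  scl <- exp(stats::runif(m, log(0.1), log(10)))
  z <- matrix(stats::rnorm(n * m, sd = config$marker_noise_sd), n, m)
  shift <- matrix(0, n, m)
  shift[, informative] <- config$marker_shift * config$marker_noise_sd *
    sign_pattern[true_cluster, , drop = FALSE]
  markers <- sweep(sweep(z + shift, 2, scl, "*"), 2, loc, "+")
  dimnames(markers) <- list(subject_ids, marker_ids)

  set.seed(config$seed + 4L)
  icv <- stats::rlnorm(n, config$icv_log_mean, config$icv_log_sd)
  baseline <- exp(stats::runif(config$n_regions, log(1500), log(20000)))
  n_effect <- config$n_regions %/% 2L
  effect_regions <- seq_len(n_effect)
  interaction_regions <- sort(sample(effect_regions,
                                     config$n_interaction_regions))
  driver_cluster <- rep_len(seq_len(cl), config$n_interaction_regions)
  sev <- c(CN = 0, MCI = 1, AD = 2)[as.integer(diagnosis)]
  sd_r <- config$volume_noise_sd * baseline
  mu <- matrix(baseline, n, config$n_regions, byrow = TRUE)
  for (j in effect_regions) {
    amp <- rep(1, n)
    ir <- match(j, interaction_regions)
    if (!is.na(ir))
      amp <- amp + config$volume_interaction_effect *
        (true_cluster == driver_cluster[ir])
    mu[, j] <- mu[, j] - config$volume_diag_effect * sev * amp * sd_r[j]
  }
  volumes <- mu + matrix(stats::rnorm(n * config$n_regions), n) %*%
    diag(sd_r, config$n_regions)
  dimnames(volumes) <- list(subject_ids, region_ids)

  set.seed(config$seed + 5L)
  d <- .demographics
  dx <- as.character(diagnosis)
  metadata <- data.frame(
    subject_id = subject_ids,
    diagnosis = dx,
    age = round(stats::rnorm(n, d$age_mean[dx], d$age_sd[dx]), 1),
    sex = ifelse(stats::runif(n) < d$female_p[dx], "F", "M"),
    education = pmax(6L, round(stats::rnorm(n, d$educ_mean[dx],
                                            d$educ_sd[dx]))),
    apoe4 = as.integer(stats::runif(n) < d$apoe4_p[dx]),
    mmse = pmin(30L, pmax(0L, round(stats::rnorm(n, d$mmse_mean[dx],
                                                 d$mmse_sd[dx])))),
    stringsAsFactors = FALSE
  )

  structure(list(
    markers = markers, volumes = volumes, icv = stats::setNames(icv, subject_ids),
    diagnosis = stats::setNames(diagnosis, subject_ids),
    true_cluster = stats::setNames(true_cluster, subject_ids),
    metadata = metadata,
    informative_markers = marker_ids[informative],
    effect_regions = region_ids[effect_regions],
    interaction_regions = stats::setNames(driver_cluster,
                                          region_ids[interaction_regions]),
    sign_pattern = sign_pattern,
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d markers, %d regions\n",
              nrow(x$markers), ncol(x$markers), ncol(x$volumes)))
  cat("  diagnosis: ",
      paste(sprintf("%s=%d", levels(x$diagnosis), table(x$diagnosis)),
            collapse = ", "), "\n", sep = "")
  cat("  clusters:  ",
      paste(sprintf("C%d=%d", seq_len(x$config$n_clusters),
                    tabulate(x$true_cluster, x$config$n_clusters)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits four RFC-4180 CSV files with a header row into `dir`:
#' `markers.csv` (subject_id plus one column per marker), `volumes.csv`
#' (subject_id, icv, one column per region), `metadata.csv` (subject_id,
#' diagnosis, age, sex, education, apoe4, mmse) and `truth.csv`
#' (subject_id, true_cluster). The first three round-trip through
#' [read_markers()], [read_volumes()] and [read_metadata()]; `truth.csv`
#' is only for post-hoc evaluation and is never consumed by the
#' clustering stages.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  paths <- c(markers = file.path(dir, "markers.csv"),
             volumes = file.path(dir, "volumes.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"))
  wr <- function(df, path) {
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path)) stop("failed to write: ", path)
  }
  wr(data.frame(subject_id = rownames(cohort$markers), cohort$markers,
                check.names = FALSE), paths["markers"])
  wr(data.frame(subject_id = rownames(cohort$volumes), icv = cohort$icv,
                cohort$volumes, check.names = FALSE), paths["volumes"])
  wr(cohort$metadata, paths["metadata"])
  wr(data.frame(subject_id = names(cohort$true_cluster),
                true_cluster = as.integer(cohort$true_cluster)),
     paths["truth"])
  invisible(paths)
}
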