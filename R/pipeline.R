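#' Run the full subtyping pipeline end to end
#'
#' Orchestrates every stage on either a simulated cohort or a set of
#' input CSVs: (optional) simulation, missing-value filtering, min-max
#' scaling, similarity learning and clustering, cluster-number report,
#' bootstrap stability, marker profiling, and permutation-corrected
#' phenotype interactions. All quantitative outputs are written as CSV,
#' plus a JSON manifest (package version, configuration, seeds) that
#' makes the run reproducible: re-running with the same manifest inputs
#' yields byte-identical CSVs. The planted truth (`truth.csv`) is never
#' read by any analysis stage; it is only consulted, when present, for
#' the optional evaluation report.
#'
#' @param dir Output directory; inputs are read from (or simulated into)
#'   `dir/input`, results written to `dir/output`.
#' @param config A [cohort_config()] to simulate from, `NULL` to use
#'   existing `markers.csv`/`volumes.csv`/`metadata.csv` in `dir/input`,
#'   or the path to a YAML file whose fields are [cohort_config()]
#'   arguments.
#' @param clusters Number of clusters; `NULL` estimates it first and
#'   uses the suggestion of [estimate_clusters()].
#' @param c_range Candidate range for the cluster-number report.
#' @param k,sigma Kernel grids (default: the `"wide"` grid, see
#'   [sigma_grid()]).
#' @param n_boot Bootstrap replicates per stability method.
#' @param stability_methods Methods to benchmark.
#' @param n_perm,alpha Permutation settings for the interaction stage.
#' @param schemes Interaction schemes to run.
#' @param top_markers How many top-ranked markers to profile.
#' @param seed Master seed (sub-seeds are derived from it).
#' @param evaluate Write `evaluation.json` (adjusted label agreement via
#'   a confusion table against `truth.csv`) when truth is available.
#' @param plots If `TRUE`, also write `plots.pdf` with the similarity
#'   heatmap and embedding.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(dir, config = cohort_config(), clusters = NULL,
                         c_range = 2:6,
                         k = NULL,
                         sigma = sigma_grid("wide")$sigma,
                         n_boot = 50,
                         stability_methods = c("cimlr", "kmeans", "random"),
                         n_perm = 200, alpha = 0.05,
                         schemes = c("whole_cluster", "diagnostic_group",
                                     "diagnostic_interaction"),
                         top_markers = 10, seed = 42L, evaluate = TRUE,
                         plots = FALSE) {
  in_dir <- file.path(dir, "input")
  out_dir <- file.path(dir, "output")
  for (d in c(in_dir, out_dir))
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop("cannot create directory: ", d)
  if (is.character(config) && length(config) == 1L)
    config <- do.call(cohort_config, yaml::read_yaml(config))
  if (!is.null(config)) {
    cohort <- generate_cohort(config)
    write_cohort(cohort, in_dir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  markers_raw <- stage("preprocess",
                       read_markers(file.path(in_dir, "markers.csv")))
  vol_in <- stage("preprocess",
                  read_volumes(file.path(in_dir, "volumes.csv")))
  metadata <- stage("preprocess",
                    read_metadata(file.path(in_dir, "metadata.csv")))
  markers_f <- stage("preprocess", filter_missing(markers_raw, metadata))
  x <- stage("preprocess", minmax_scale(markers_f))
  volumes <- stage("preprocess",
                   normalize_volumes(vol_in$volumes, vol_in$icv))

  bank <- stage("kernels", kernel_bank(x, k = k, sigma = sigma))
  est <- stage("model_selection",
               estimate_clusters(x, c_range = c_range, scale = FALSE,
                                 bank = bank, seed = seed + 1L))
  C <- if (is.null(clusters)) est$suggested else as.integer(clusters)
  fit <- stage("fit", cimlr(bank, clusters = C, seed = seed + 2L))

  stab <- stage("stability", lapply(stats::setNames(stability_methods,
                                                    stability_methods),
    function(m) cluster_stability(x, fit$labels, method = m,
                                  n_boot = n_boot, clusters = C,
                                  seed = seed + 3L,
                                  k = k, sigma = sigma)))

  imp <- stage("profiling", marker_importance(fit))
  prof <- stage("profiling",
                cluster_profiles(x, fit$labels,
                                 markers = utils::head(imp$marker,
                                                       top_markers)))
  diagnosis <- metadata$diagnosis[match(rownames(volumes),
                                        metadata$subject_id)]
  inter <- stage("interaction",
                 interaction_analysis(volumes, fit$labels[rownames(volumes)],
                                      diagnosis, schemes = schemes,
                                      n_perm = n_perm, alpha = alpha,
                                      seed = seed + 4L))

  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(data.frame(subject_id = names(fit$labels),
                  cluster = as.integer(fit$labels)), "labels.csv")
  wcsv(est$table, "cluster_estimate.csv")
  wcsv(imp, "importance.csv")
  wcsv(prof, "profiles.csv")
  wcsv(do.call(rbind, lapply(names(stab), function(m)
    data.frame(method = m, cluster = names(stab[[m]]$mean_jaccard),
               mean_jaccard = as.numeric(stab[[m]]$mean_jaccard),
               n_boot = n_boot, seed = seed + 3L))), "stability.csv")
  wcsv(inter, "interactions.csv")

  manifest <- list(
    package = "markerclust",
    version = as.character(utils::packageVersion("markerclust")),
    seed = seed, clusters = C, c_range = c_range,
    kernel_grid = list(k = k, sigma = sigma),
    n_boot = n_boot, n_perm = n_perm, alpha = alpha,
    schemes = schemes,
    config = if (is.null(config)) NULL else unclass(config),
    estimate = list(separation_set = est$separation_set,
                    elbow_set = est$elbow_set,
                    suggested = est$suggested),
    n_subjects = nrow(x), n_markers = ncol(x),
    n_kernels = nrow(bank$params),
    converged = fit$converged
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  evaluation <- NULL
  truth_path <- file.path(in_dir, "truth.csv")
  if (evaluate && file.exists(truth_path)) {
    truth <- utils::read.csv(truth_path)
    tc <- truth$true_cluster[match(names(fit$labels), truth$subject_id)]
    conf <- table(truth = tc, fitted = fit$labels)
    evaluation <- list(confusion = as.data.frame(conf),
                       agreement = .rand_adjusted(tc, fit$labels))
    jsonlite::write_json(list(adjusted_rand = evaluation$agreement),
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (plots) {
    grDevices::pdf(file.path(out_dir, "plots.pdf"), width = 10, height = 5)
    graphics::par(mfrow = c(1, 2))
    plot(fit)
    grDevices::dev.off()
  }

  invisible(list(fit = fit, estimate = est, stability = stab,
                 importance = imp, profiles = prof,
                 interactions = inter, evaluation = evaluation,
                 manifest = manifest))
}

# adjusted Rand index between two labelings (closed-form from the
# contingency table)
.rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
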