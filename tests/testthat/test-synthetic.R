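test_that("invalid configurations are rejected", {
  expect_error(cohort_config(cluster_proportions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(cohort_config(n_informative = 200, n_markers = 100),
               "n_informative")
  expect_error(cohort_config(n_clusters = 3), "length n_clusters")
  expect_error(cohort_config(n_interaction_regions = 30, n_regions = 40),
               "diagnosis-effect regions")
  # a stratum whose expected size is below 2 cannot support group tests
  expect_error(cohort_config(n_subjects = 20,
                             diag_proportions = c(0.05, 0.65, 0.3)),
               "diagnostic group")
  expect_error(cohort_config(n_subjects = 40, n_clusters = 2,
                             cluster_proportions = c(0.02, 0.98)),
               "smallest cluster")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- cohort_config(n_subjects = 40, n_markers = 12, n_regions = 8,
                       n_informative = 4, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_subjects = 40, n_markers = 12,
                                      n_regions = 8, n_informative = 4,
                                      seed = 6))
  expect_false(identical(a$markers, c2$markers))
})

test_that("diagnosis mixture matches the configured proportions", {
  coh <- generate_cohort(cohort_config(seed = 2))
  counts <- table(coh$diagnosis)
  # multinomial draw around (52, 161, 85) out of 298
  p <- chisq.test(counts, p = c(52, 161, 85) / 298)$p.value
  expect_gt(p, 1e-3)
  expect_equal(sum(counts), 298)
})

test_that("diagnosis is independent of the planted cluster", {
  n_pass <- 0
  for (s in 1:20) {
    coh <- small_cohort(seed = s, n_subjects = 160)
    p <- suppressWarnings(
      chisq.test(table(coh$true_cluster, coh$diagnosis))$p.value)
    n_pass <- n_pass + (p > 0.01)
  }
  expect_gte(n_pass, 18)
})

test_that("zero marker shift leaves informative markers at noise level", {
  coh <- generate_cohort(cohort_config(n_subjects = 150, n_markers = 60,
                                       n_informative = 10,
                                       marker_shift = 0, n_regions = 10,
                                       seed = 3))
  ps <- apply(coh$markers, 2, function(v)
    oneway.test(v ~ factor(coh$true_cluster), var.equal = TRUE)$p.value)
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("planted structure is recoverable from informative columns alone", {
  # brute-force check, independent of the similarity-learning pipeline
  for (s in 1:3) {
    coh <- small_cohort(seed = s, n_subjects = 120, n_markers = 40,
                        n_informative = 8)
    x <- minmax_scale(coh$markers)[, coh$informative_markers]
    km <- kmeans(x, centers = 4, nstart = 30)
    expect_gte(ari(km$cluster, coh$true_cluster), 0.95)
  }
})

test_that("volumes carry the planted atrophy ordering and interaction", {
  coh <- generate_cohort(cohort_config(seed = 4))
  r <- coh$effect_regions[!coh$effect_regions %in%
                            names(coh$interaction_regions)][1]
  m <- tapply(coh$volumes[, r], coh$diagnosis, mean)
  expect_true(m["CN"] > m["MCI"] && m["MCI"] > m["AD"])
  # interaction region: the driver cluster's MCI subjects lose extra volume
  ir <- names(coh$interaction_regions)[1]
  drv <- coh$interaction_regions[[1]]
  mci <- coh$diagnosis == "MCI"
  expect_lt(mean(coh$volumes[mci & coh$true_cluster == drv, ir]),
            mean(coh$volumes[mci & coh$true_cluster != drv, ir]))
})

test_that("cohorts round-trip through the CSV writers and readers", {
  coh <- small_cohort(seed = 9, n_subjects = 20, n_markers = 6,
                      n_regions = 5, n_clusters = 2)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  m <- read_markers(paths[["markers"]])
  expect_equal(m, coh$markers, tolerance = 1e-12)
  v <- read_volumes(paths[["volumes"]])
  expect_equal(v$volumes, coh$volumes, tolerance = 1e-12)
  expect_equal(v$icv, coh$icv, tolerance = 1e-12)
  md <- read_metadata(paths[["metadata"]])
  expect_equal(nrow(md), 20)
  expect_s3_class(md$diagnosis, "factor")
  expect_equal(as.character(md$diagnosis),
               as.character(coh$metadata$diagnosis))
})

test_that("write_cohort surfaces the offending path on failure", {
  coh <- small_cohort(seed = 9, n_subjects = 20, n_markers = 4,
                      n_regions = 4, n_clusters = 2)
  expect_error(write_cohort(coh, "/proc/definitely/not/writable"),
               "directory")
})
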