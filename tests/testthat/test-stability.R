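test_that("the Jaccard index follows set arithmetic", {
  expect_equal(jaccard_index(1:3, 1:3), 1)
  expect_equal(jaccard_index(1:2, 3:4), 0)
  expect_equal(jaccard_index(1:3, 2:4), 0.5)
  expect_equal(jaccard_index(c(1, 1, 2), c(2, 2, 1)), 1)  # duplicates collapse
  expect_warning(j <- jaccard_index(integer(0), integer(0)), "empty")
  expect_equal(j, 0)
  # brute-force oracle on random set pairs
  set.seed(5)
  for (r in 1:100) {
    a <- sample(20, sample(0:10, 1))
    b <- sample(20, sample(1:10, 1))
    expected <- length(intersect(a, b)) /
      (length(a) + length(b) - length(intersect(a, b)))
    expect_equal(jaccard_index(a, b), expected)
  }
})

test_that("relabelled clusterings are matched back perfectly", {
  set.seed(2)
  labels <- sample(1:4, 40, replace = TRUE)
  names(labels) <- paste0("s", 1:40)
  perm <- c(3, 1, 4, 2)
  cand <- setNames(perm[labels], names(labels))
  m <- match_clusters(labels, cand)
  expect_equal(m$total, 4)
  expect_true(all(m$jaccard == 1))
  expect_equal(unname(m$mapping[order(as.integer(names(m$mapping)))]),
               order(perm))
  ident <- match_clusters(labels, labels)
  expect_equal(unname(ident$mapping), 1:4)
})

test_that("optimal matching agrees with exhaustive search", {
  # 6-subject toy with one swapped subject
  ref <- setNames(c(1, 1, 2, 2, 3, 3), paste0("s", 1:6))
  cand <- setNames(c(1, 1, 2, 3, 3, 2), paste0("s", 1:6))
  m <- match_clusters(ref, cand)
  bf <- brute_force_match(labels_to_sets(ref), labels_to_sets(cand))
  expect_equal(m$total, bf$total)
  expect_equal(unname(m$jaccard), bf$jaccard)
  # randomised property, including unequal cluster counts
  set.seed(6)
  for (r in 1:25) {
    ref <- sample(1:sample(2:4, 1), 15, replace = TRUE)
    cand <- sample(1:sample(2:5, 1), 15, replace = TRUE)
    m <- match_clusters(ref, cand)
    bf <- brute_force_match(labels_to_sets(ref), labels_to_sets(cand))
    expect_equal(m$total, bf$total, tolerance = 1e-12)
  }
})

test_that("a self-resample reproduces the reference clusters exactly", {
  coh <- small_cohort(n_subjects = 60, n_markers = 20, n_clusters = 3,
                      seed = 4)
  fit <- cimlr(coh$markers, clusters = 3, embed = FALSE, seed = 1)
  rep1 <- cluster_stability(coh$markers, fit$labels, method = "cimlr",
                            n_boot = 1, seed = 1,
                            indices = list(seq_len(60)))
  expect_equal(unname(rep1$mean_jaccard), rep(1, 3))
})

test_that("stability reports are reproducible and bounded", {
  coh <- small_cohort(n_subjects = 50, n_markers = 15, n_clusters = 2,
                      seed = 5)
  fit <- cimlr(coh$markers, clusters = 2, embed = FALSE, seed = 1)
  r1 <- cluster_stability(coh$markers, fit$labels, method = "kmeans",
                          n_boot = 10, seed = 42)
  r2 <- cluster_stability(coh$markers, fit$labels, method = "kmeans",
                          n_boot = 10, seed = 42)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_true(all(r1$per_replicate >= 0 & r1$per_replicate <= 1))
  expect_equal(unname(r1$mean_jaccard), unname(colMeans(r1$per_replicate)))
  expect_output(print(r1), "kmeans")
})

test_that("random labels score the chance baseline", {
  # the package's random-method mean must agree with an independent
  # direct simulation of random set overlap under optimal matching
  coh <- small_cohort(n_subjects = 60, n_markers = 15, n_clusters = 3,
                      seed = 6)
  fit <- cimlr(coh$markers, clusters = 3, embed = FALSE, seed = 1)
  rep_pkg <- cluster_stability(coh$markers, fit$labels,
                               method = "random", n_boot = 60, seed = 9)
  ids <- rownames(coh$markers)
  ref_sets <- labels_to_sets(fit$labels, ids)
  set.seed(1234)
  sims <- replicate(300, {
    idx <- sample(60, 60, replace = TRUE)
    uids <- unique(ids[idx])
    cand <- lapply(split(ids[idx], sample(1:3, 60, replace = TRUE)),
                   unique)
    length(cand) <- 3
    cand[vapply(cand, is.null, TRUE)] <- list(character(0))
    ref_here <- lapply(ref_sets, intersect, uids)
    mean(brute_force_match(ref_here, cand)$jaccard)
  })
  mc_sd <- sd(sims) / sqrt(length(sims)) +
    sd(rowMeans(rep_pkg$per_replicate)) / sqrt(rep_pkg$n_boot)
  expect_lt(abs(mean(rep_pkg$mean_jaccard) - mean(sims)), 3 * mc_sd)
})
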