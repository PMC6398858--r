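test_that("Mann-Whitney p-values match the documented conventions", {
  expect_equal(mann_whitney(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(mann_whitney(1:4, 10:13), 2 / choose(8, 4))
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
  expect_error(mann_whitney(1, 2), "at least 4")
})

test_that("exact p-values agree with full enumeration", {
  # oracle: enumerate every assignment of the pooled values into the
  # two groups and tabulate the exact U distribution
  enum_p <- function(a, b) {
    pool <- c(a, b)
    n1 <- length(a)
    r <- rank(pool)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(utils::combn(length(pool), n1), 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    min(2 * min(mean(us <= u_obs), mean(us >= u_obs)), 1)
  }
  set.seed(10)
  for (r in 1:20) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    vals <- sample(seq_len(50), n1 + n2)   # tie-free
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    expect_equal(mann_whitney(a, b), enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("the test holds its size under the null", {
  set.seed(11)
  rej <- mean(replicate(4000, {
    mann_whitney(rnorm(10), rnorm(10)) < 0.05
  }))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("the fast rank-based path reproduces wilcox.test exactly", {
  set.seed(12)
  for (r in 1:300) {
    n1 <- sample(2:25, 1)
    n2 <- sample(2:25, 1)
    vals <- if (runif(1) < 0.5) round(rnorm(n1 + n2), 1) else
      rnorm(n1 + n2)
    prep <- markerclust:::.mw_prepare(vals)
    fast <- markerclust:::.mw_p(prep, seq_len(n1))
    expect_equal(fast,
                 mann_whitney(vals[seq_len(n1)], vals[-seq_len(n1)]),
                 tolerance = 1e-12)
  }
})

test_that("stratified shuffles preserve every cluster-diagnosis cell", {
  set.seed(13)
  labels <- sample(1:4, 120, replace = TRUE)
  strata <- sample(c("CN", "MCI", "AD"), 120, replace = TRUE)
  ref <- table(labels, strata)
  for (r in 1:200) {
    p <- permute_labels(labels, strata)
    expect_identical(table(p, strata), ref, ignore_attr = TRUE)
  }
})

test_that("one subject per stratum forces the identity permutation", {
  labels <- c(1, 2, 3)
  strata <- c("a", "b", "c")
  expect_identical(permute_labels(labels, strata, seed = 1), labels)
})

test_that("stratified shuffles are uniform over admissible assignments", {
  # 6-subject toy, two strata of 3; each stratum has 3! arrangements,
  # 36 admissible assignments in total
  labels <- c(1, 2, 3, 1, 2, 3)
  strata <- rep(c("x", "y"), each = 3)
  set.seed(14)
  n <- 9000
  seen <- table(replicate(n, paste(permute_labels(labels, strata),
                                   collapse = "")))
  expect_equal(length(seen), 36)
  p0 <- 1 / 36
  band <- 3 * sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(seen / n - p0) < band + 1e-9))
})

test_that("comparison groups follow each scheme's definition", {
  labels <- c(1, 1, 2, 2, 2, 1)
  dx <- factor(c("CN", "MCI", "CN", "MCI", "AD", "AD"),
               levels = c("CN", "MCI", "AD"))
  g <- markerclust:::.comparison_groups("whole_cluster", labels, dx, 1)
  expect_equal(g$a, c(1, 2, 6))
  expect_equal(g$b, c(3, 4, 5))
  g <- markerclust:::.comparison_groups("diagnostic_group", labels, dx, 2,
                                        pair = c("CN", "MCI"))
  expect_equal(g$a, 3)
  expect_equal(g$b, 4)
  g <- markerclust:::.comparison_groups("diagnostic_interaction", labels,
                                        dx, 1, group = "CN")
  expect_equal(g$a, 1)
  expect_equal(g$b, 3)
})

test_that("a dominant observed effect is flagged at any alpha", {
  set.seed(15)
  n <- 80
  labels <- rep(1:2, each = n / 2)
  dx <- factor(rep(c("CN", "MCI"), n / 2), levels = c("CN", "MCI", "AD"))
  phen <- rnorm(n) + 3 * (labels == 1)
  res <- compare_phenotype(phen, labels, dx, scheme = "whole_cluster",
                           cluster = 1, n_perm = 100, seed = 3)
  expect_true(res$significant)
  expect_lte(res$observed_p, min(res$null_ps))
  for (a in c(0.01, 0.5, 1)) {
    expect_lte(res$observed_p, unname(quantile(res$null_ps, a)))
  }
})

test_that("undersized observed groups are an error naming the spec", {
  labels <- c(1, rep(2, 19))
  dx <- factor(rep(c("CN", "MCI"), 10), levels = c("CN", "MCI", "AD"))
  phen <- rnorm(20)
  expect_error(compare_phenotype(phen, labels, dx,
                                 scheme = "whole_cluster", cluster = 1,
                                 n_perm = 10),
               "whole_cluster, cluster 1")
})

test_that("permutation results are reproducible for a fixed seed", {
  coh <- small_cohort(seed = 16, n_subjects = 90)
  phen <- normalize_volumes(coh$volumes, coh$icv)
  r1 <- compare_phenotype(phen[, 1], coh$true_cluster, coh$diagnosis,
                          scheme = "diagnostic_interaction", cluster = 1,
                          group = "MCI", n_perm = 50, seed = 21)
  r2 <- compare_phenotype(phen[, 1], coh$true_cluster, coh$diagnosis,
                          scheme = "diagnostic_interaction", cluster = 1,
                          group = "MCI", n_perm = 50, seed = 21)
  expect_identical(r1$null_ps, r2$null_ps)
  expect_identical(r1$significant, r2$significant)
})

test_that("the results table enumerates the expected comparisons", {
  coh <- small_cohort(seed = 17, n_subjects = 120, n_clusters = 2,
                      n_regions = 6)
  phen <- normalize_volumes(coh$volumes, coh$icv)
  tab <- interaction_analysis(phen, coh$true_cluster, coh$diagnosis,
                              schemes = "whole_cluster", n_perm = 20,
                              seed = 1)
  expect_equal(nrow(tab), 2 * 6)
  tab2 <- interaction_analysis(phen[, 1:2], coh$true_cluster,
                               coh$diagnosis,
                               schemes = "diagnostic_group", n_perm = 20,
                               seed = 1)
  expect_equal(nrow(tab2), 2 * 3 * 2)   # clusters x pairs x phenotypes
  # undersized cells surface as skipped rows, not dropped rows
  expect_true(all(tab2$status[is.na(tab2$observed_p)] != "ok") ||
                all(!is.na(tab2$observed_p)))
  tab3 <- interaction_analysis(phen[, 1:2], coh$true_cluster,
                               coh$diagnosis,
                               schemes = "diagnostic_group", n_perm = 20,
                               seed = 1)
  expect_identical(tab2$significant, tab3$significant)
})
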