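make_matrix <- function(areas, groups) {
  out <- cbind(data.frame(mz = seq_len(nrow(areas)) + 100,
                          rt_s = seq_len(nrow(areas)) * 2), areas)
  attr(out, "groups") <- groups
  class(out) <- c("feature_matrix", "data.frame")
  out
}

grp6 <- setNames(rep(c("control", "treated"), each = 3),
                 c("C1", "C2", "C3", "T1", "T2", "T3"))

test_that("volcano handles null features, spikes and degenerate input", {
  areas <- data.frame(C1 = c(10, 100), C2 = c(10, 110), C3 = c(10, 90),
                      T1 = c(10, 1000), T2 = c(10, 1100), T3 = c(10, 950))
  mat <- make_matrix(areas, grp6)
  v <- volcano(mat, "control", "treated")
  expect_equal(v$log2fc[1], 0)
  expect_false(v$selected[1])
  expect_true(v$selected[2])       # ~10x spike, clearly significant
  expect_true(all(v$p >= 0 & v$p <= 1))
  # fewer than 2 samples per group is an error
  g2 <- setNames(c("control", "treated", "treated"), c("C1", "T1", "T2"))
  m2 <- make_matrix(data.frame(C1 = 1, T1 = 2, T2 = 3), g2)
  expect_error(volcano(m2, "control", "treated"), "at least 2 samples")
})

test_that("volcano type-I error on a null study is near alpha", {
  set.seed(41)
  n_feat <- 500
  areas <- as.data.frame(matrix(2^rnorm(n_feat * 6, mean = 17, sd = 0.5),
                                n_feat, 6))
  names(areas) <- names(grp6)
  v <- volcano(make_matrix(areas, grp6), "control", "treated")
  frac <- mean(v$p <= 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("a 10x spike with 10% CV is selected at fc 2, alpha 0.05", {
  set.seed(42)
  base <- 1e5
  areas <- data.frame(C1 = base * rlnorm(1, 0, 0.1),
                      C2 = base * rlnorm(1, 0, 0.1),
                      C3 = base * rlnorm(1, 0, 0.1),
                      T1 = 10 * base * rlnorm(1, 0, 0.1),
                      T2 = 10 * base * rlnorm(1, 0, 0.1),
                      T3 = 10 * base * rlnorm(1, 0, 0.1))
  v <- volcano(make_matrix(areas, grp6), "control", "treated",
               fc_thresh = 2, alpha = 0.05)
  expect_true(v$selected[1])
  expect_gt(v$log2fc[1], log2(5))
})

test_that("volcano is antisymmetric in group order and scale invariant", {
  set.seed(43)
  areas <- as.data.frame(matrix(2^rnorm(120, 15, 1), 20, 6))
  names(areas) <- names(grp6)
  areas[3, 1:2] <- NA               # absent in some controls
  mat <- make_matrix(areas, grp6)
  v1 <- volcano(mat, "control", "treated")
  v2 <- volcano(mat, "treated", "control")
  expect_equal(v1$log2fc, -v2$log2fc, tolerance = 1e-12)
  expect_equal(v1$p, v2$p, tolerance = 1e-12)
  scaled <- make_matrix(areas * 1e3, grp6)
  v3 <- volcano(scaled, "control", "treated")
  expect_equal(v1$p, v3$p, tolerance = 1e-9)
  expect_equal(v1$log2fc, v3$log2fc, tolerance = 1e-9)
})

test_that("anova_tukey flags the shifted group and handles degeneracy", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(11, 12, 13))
  res <- anova_tukey(g)
  expect_lt(res$p_value, 0.001)
  pw <- res$pairwise
  p_ba <- pw$p[(pw$group1 == "b" & pw$group2 == "a") |
                 (pw$group1 == "a" & pw$group2 == "b")]
  expect_gt(p_ba, 0.05)
  expect_true(all(pw$p[grepl("c", paste(pw$group1, pw$group2))] < 0.05))
  # a 1e5-label-permutation reference reproduces the significance pattern
  # (permutation tails are granular on 9 discrete values, so only the
  # pattern, not the exact p, is comparable)
  set.seed(44)
  p_ref <- perm_tukey_ref(g, B = 1e5)
  expect_identical(p_ref <= 0.05, pw$p <= 0.05)
  # a Monte-Carlo studentized-range null reproduces the p-values themselves
  set.seed(48)
  qnull <- mc_q_null(3, 3, B = 4e5)
  m <- vapply(g, mean, numeric(1))
  s2 <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) / 6
  for (j in seq_len(nrow(pw))) {
    qobs <- abs(m[pw$group1[j]] - m[pw$group2[j]]) / sqrt(s2 / 3)
    expect_lt(abs(pw$p[j] - mean(qnull >= qobs)), 0.005)
  }
  # degenerate: all values identical
  expect_warning(r0 <- anova_tukey(list(a = c(1, 1), b = c(1, 1),
                                        c = c(1, 1))), "zero total variance")
  expect_equal(r0$p_value, 1)
  expect_true(all(r0$pairwise$p == 1))
  expect_error(anova_tukey(list(a = 1:3)), "at least 2 groups")
  expect_error(anova_tukey(list(a = 1:3, b = 2)), "at least 2 values")
})

test_that("two-group Tukey reduces to the pooled-variance t-test", {
  set.seed(45)
  for (i in 1:5) {
    g <- list(a = rnorm(4, 0, 1), b = rnorm(5, 0.8, 1))
    res <- anova_tukey(g)
    tt <- t.test(g$b, g$a, var.equal = TRUE)
    expect_equal(res$pairwise$p, tt$p.value, tolerance = 1e-6)
  }
})

test_that("Tukey pairwise p matches a Monte-Carlo studentized-range null", {
  set.seed(46)
  k <- 3; n <- 4
  qnull <- mc_q_null(k, n, B = 4e5)
  worst <- 0
  for (i in 1:20) {
    g <- list(a = rnorm(n, 0, 1), b = rnorm(n, runif(1, 0, 2), 1),
              c = rnorm(n, runif(1, 0, 2), 1))
    res <- anova_tukey(g)
    m <- vapply(g, mean, numeric(1))
    s2 <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) /
      (k * (n - 1))
    cmb <- utils::combn(names(g), 2)
    for (j in seq_len(ncol(cmb))) {
      qobs <- abs(m[cmb[1, j]] - m[cmb[2, j]]) / sqrt(s2 / n)
      p_mc <- mean(qnull >= qobs)
      p_pkg <- res$pairwise$p[
        (res$pairwise$group1 == cmb[1, j] &
           res$pairwise$group2 == cmb[2, j]) |
          (res$pairwise$group1 == cmb[2, j] &
             res$pairwise$group2 == cmb[1, j])]
      worst <- max(worst, abs(p_pkg - p_mc))
    }
  }
  expect_lt(worst, 0.005)
})
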