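test_that("one-way ANOVA handles its boundary cases", {
  # two groups with identical value sets: no between-group signal
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  fit <- anova_oneway(v, g)
  expect_equal(fit$F_stat, 0)
  expect_equal(fit$p_value, 1)
  expect_error(anova_oneway(rep(5, 8), g),
               class = "alleloscreen_degenerate_anova")
  expect_error(anova_oneway(1:4, rep("a", 4)), "2 groups")
  expect_error(anova_oneway(1:4, c("a", "a", "a", "b")), ">= 2 replicates")
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(88)
  for (i in 1:20) {
    v <- rnorm(12)
    g <- rep(c("a", "b"), each = 6)
    fit <- anova_oneway(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(fit$F_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Duncan letters collapse and separate as expected", {
  # all groups drawn identically close: one shared letter
  v <- c(10.0, 10.1, 9.9, 10.0, 10.05, 9.95, 10.1, 10.0, 9.9, 10.0, 10.1, 10.05)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- duncan_mrt(v, g)
  expect_true(all(res$letters == "a"))
  # wildly separated means: all letters distinct
  v2 <- c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1), rnorm(4, 20, 0.1))
  res2 <- duncan_mrt(v2, g)
  expect_identical(sort(unique(res2$letters)), c("a", "b", "c"))
})

test_that("two-group Duncan decision equals the pooled t test at alpha", {
  set.seed(19)
  for (i in 1:50) {
    v <- rnorm(8, sd = 1) + rep(c(0, runif(1, 0, 2)), each = 4)
    g <- rep(c("a", "b"), each = 4)
    res <- duncan_mrt(v, g, alpha = 0.05)
    separated <- length(unique(res$letters)) == 2
    t_reject <- t.test(v ~ g, var.equal = TRUE)$p.value < 0.05
    expect_identical(separated, t_reject)
  }
})

test_that("Duncan letters match the exhaustive span oracle", {
  for (s in 1:50) {
    set.seed(1300 + s)
    k <- sample(3:6, 1)
    g <- rep(letters[1:k], each = 4)
    v <- rnorm(4 * k, mean = rep(runif(k, 0, 3), each = 4))
    res <- duncan_mrt(v, g)
    expect_identical(res$letters, oracle_duncan_letters(v, g))
  }
})

test_that("unbalanced designs use the harmonic mean and are flagged", {
  set.seed(3)
  v <- rnorm(11, mean = rep(c(0, 1, 5), times = c(4, 4, 3)))
  g <- rep(c("a", "b", "c"), times = c(4, 4, 3))
  res <- duncan_mrt(v, g)
  expect_false(res$balanced)
  expect_equal(res$n_harmonic, 3 / (1 / 4 + 1 / 4 + 1 / 3))
  expect_identical(res$letters, oracle_duncan_letters(v, g))
})

test_that("percent change is exact, antisymmetric in sign and guarded", {
  expect_identical(percent_change(2, 1), 100)
  expect_identical(percent_change(1, 2), -50)
  expect_identical(percent_change(1, 1), 0)
  expect_error(percent_change(1, 0), "strictly positive")
  set.seed(6)
  m <- runif(20, 0.1, 10); c <- runif(20, 0.1, 10)
  expect_identical(sign(percent_change(m, c)), sign(m - c))
  expect_identical(percent_change(c, c), rep(0, 20))
})

test_that("permutation importance finds a planted dominant predictor", {
  set.seed(10)
  x <- as.data.frame(matrix(runif(60 * 4), 60, 4))
  y <- x[[2]]
  imp <- importance_ranking(x, y, n_rounds = 20, ntree = 200, seed = 1)
  expect_identical(imp$variable[1], "V2")
  expect_identical(sort(imp$rank), 1:4)
  expect_error(importance_ranking(x[1:5, ], y[1:5]), "at least 8")
  expect_error(importance_ranking(x, rep(1, 60)), "constant response")
})

test_that("duplicated feature columns split the importance mass", {
  set.seed(11)
  x <- data.frame(a = runif(80), b = runif(80))
  x$a2 <- x$a
  y <- x$a + rnorm(80, sd = 0.05)
  imp <- importance_ranking(x, y, n_rounds = 30, ntree = 300, seed = 2)
  ia <- imp$importance[imp$variable == "a"]
  ia2 <- imp$importance[imp$variable == "a2"]
  ib <- imp$importance[imp$variable == "b"]
  # each duplicate keeps substantial importance; the noise column has ~none
  expect_gt(ia, ib); expect_gt(ia2, ib)
  solo <- importance_ranking(x[c("a", "b")], y, n_rounds = 30, ntree = 300,
                             seed = 2)
  expect_lt(ia, solo$importance[solo$variable == "a"])
})

test_that("importance runs are reproducible under a fixed seed", {
  set.seed(12)
  x <- as.data.frame(matrix(runif(60 * 3), 60, 3))
  y <- x[[1]] + rnorm(60, sd = 0.1)
  i1 <- importance_ranking(x, y, n_rounds = 10, ntree = 100, seed = 42)
  i2 <- importance_ranking(x, y, n_rounds = 10, ntree = 100, seed = 42)
  expect_equal(i1$importance, i2$importance)
})

make_physio <- function(centers, n_bio = 4, n_tech = 3, sd = 0.05,
                        seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(centers), function(g) {
    do.call(rbind, lapply(seq_len(n_bio), function(b) {
      mu <- centers[[g]] * (1 + rnorm(length(centers[[g]]), 0, sd))
      data.frame(treatment = g, bio_rep = b, tech_rep = rep(1:n_tech,
                 each = length(mu)),
                 indicator = rep(names(centers[[g]]), n_tech),
                 value = rep(mu, n_tech) * (1 + rnorm(length(mu) * n_tech,
                                                      0, sd / 2)))
    }))
  }))
}

test_that("PCA profiles satisfy trace conservation and centering", {
  centers <- list(
    CK = c(A = 1, B = 2, C = 3, D = 1),
    T1 = c(A = 3, B = 1, C = 2, D = 2),
    T10 = c(A = 2, B = 3, C = 1, D = 3))
  pca <- pca_profiles(make_physio(centers, seed = 21))
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-10)
  score_cols <- grep("^PC", names(pca$scores))
  expect_true(all(abs(colMeans(pca$scores[score_cols])) < 1e-10))
  # deterministic sign: leading loading of each component is positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("collinear samples load a single component", {
  # samples exactly on a line in indicator space
  base <- seq(0.5, 4, length.out = 8)
  physio <- do.call(rbind, lapply(seq_along(base), function(i) {
    data.frame(treatment = paste0("G", (i - 1) %/% 4 + 1),
               bio_rep = (i - 1) %% 4 + 1, tech_rep = 1,
               indicator = c("A", "B", "C"),
               value = base[i] * c(1, 2, 3))
  }))
  pca <- pca_profiles(physio)
  expect_equal(unname(pca$var_explained[1]), 1, tolerance = 1e-10)
})

test_that("zero-variance indicators are dropped with a warning", {
  centers <- list(CK = c(A = 1, B = 2, C = 1), T1 = c(A = 2, B = 1, C = 1))
  ph <- make_physio(centers, seed = 5)
  ph$value[ph$indicator == "C"] <- 7
  expect_warning(pca <- pca_profiles(ph), "zero-variance")
  expect_false("C" %in% rownames(pca$loadings))
})

test_that("well-separated treatments form distinct PCA groups", {
  centers <- list(
    CK = c(A = 1, B = 1, C = 1, D = 1, E = 1),
    T1 = c(A = 3, B = 3, C = 0.4, D = 1, E = 2),
    T10 = c(A = 0.5, B = 1.8, C = 3, D = 2.5, E = 0.6))
  pca <- pca_profiles(make_physio(centers, sd = 0.04, seed = 33))
  sil <- cluster::silhouette(as.integer(factor(pca$scores$treatment)),
                             dist(pca$scores[, c("PC1", "PC2")]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("radar profiles min-max scale each indicator to [0, 1]", {
  ph <- data.frame(treatment = rep(c("CK", "T1", "T10"), 2),
                   indicator = rep(c("MDA", "SOD"), each = 3),
                   value = c(1, 2, 3, 5, 5, 5))
  expect_warning(rad <- radar_profile(ph), "constant indicator")
  mda <- rad$value[rad$indicator == "MDA"][order(rad$treatment[rad$indicator == "MDA"])]
  expect_equal(sort(rad$value[rad$indicator == "MDA"]), c(0, 0.5, 1))
  expect_true(all(rad$value[rad$indicator == "SOD"] == 0.5))
  expect_true(all(rad$value >= 0 & rad$value <= 1))
  expect_error(radar_profile(ph[ph$treatment == "CK", ]), ">= 2 treatments")
})
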