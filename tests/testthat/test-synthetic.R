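test_that("design and effect constructors validate their inputs", {
  expect_s3_class(allelo_design(treatments = "T1", seed = 1), "allelo_design")
  expect_error(allelo_design(treatments = c("CK", "T1"), control = "CK"),
               "control label")
  expect_error(allelo_design(treatments = c("T1", "T1")), "duplicated")
  expect_error(allelo_design(treatments = "T1", seeds_per_dish = 0),
               "positive integer")
  expect_error(treatment_effect(p_germ_day7 = 1.2), "\\[0, 1\\]")
  expect_error(treatment_effect(0.5, mean_height_cm = -1), "positive")
  expect_error(treatment_effect(0.5, physio_multipliers = c(MDA = -2)),
               "positive")
  expect_error(treatment_effect(0.5, physio_multipliers = c(XYZ = 1)),
               "unknown physiology indicator")
})

test_that("degenerate germination probabilities produce the forced counts", {
  d <- allelo_design(treatments = "T1", seed = 3)
  full <- list(CK = treatment_effect(1, 1), T1 = treatment_effect(1, 1))
  sim <- simulate_germination(d, full)
  expect_true(all(sim$dishes$n3 == 30 & sim$dishes$n7 == 30))
  none <- list(CK = treatment_effect(0), T1 = treatment_effect(0))
  sim0 <- simulate_germination(d, none)
  expect_true(all(sim0$dishes$n7 == 0 & sim0$dishes$n3 == 0))
  expect_identical(nrow(sim0$seedlings), 0L)
})

test_that("generation errors on unknown or missing treatment labels", {
  d <- allelo_design(treatments = "T1", seed = 3)
  expect_error(simulate_germination(d, list(CK = treatment_effect(0.5))),
               "missing: T1")
  expect_error(
    simulate_germination(d, list(CK = treatment_effect(0.5),
                                 T1 = treatment_effect(0.5),
                                 T9 = treatment_effect(0.5))),
    "unknown treatment label")
})

test_that("count ordering n3 <= n7 <= n_total holds across generated dishes", {
  d <- allelo_design(dishes_per_treatment = 10, seed = 99)
  eff <- demo_effects(d)
  sim <- simulate_germination(d, eff)
  expect_true(all(sim$dishes$n3 <= sim$dishes$n7))
  expect_true(all(sim$dishes$n7 <= sim$dishes$n_total))
  expect_true(all(sim$seedlings$radicle_mm > 0))
  expect_true(all(sim$seedlings$height_cm > 0))
  # seedling rows match the germinated counts
  per_dish <- table(paste(sim$seedlings$treatment, sim$seedlings$dish_id))
  nz <- sim$dishes[sim$dishes$n7 > 0, ]
  expect_identical(as.integer(per_dish[paste(nz$treatment, nz$dish_id)]),
                   as.integer(nz$n7))
})

test_that("empirical germination fraction converges to p_germ_day7", {
  # 1,000 regenerated 4-dish x 30-seed datasets at p = 0.8
  p <- 0.8
  eff <- list(CK = treatment_effect(p), T1 = treatment_effect(p))
  means <- vapply(seq_len(1000), function(i) {
    d <- allelo_design(treatments = "T1", seed = 12345 + i)
    sim <- simulate_germination(d, eff)
    sub <- sim$dishes[sim$dishes$treatment == "T1", ]
    mean(sub$n7 / sub$n_total)
  }, numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - p), 3 * mc_se)
})

test_that("fixed-seed reruns are byte-identical and seeds matter", {
  d <- allelo_design(seed = 777)
  eff <- demo_effects(d)
  s1 <- simulate_germination(d, eff)
  s1$physiology <- simulate_physiology(d, eff)
  s2 <- simulate_germination(d, eff)
  s2$physiology <- simulate_physiology(d, eff)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_bioassay_csv(s1, dir1)
  write_bioassay_csv(s2, dir2)
  for (f in c("germination.csv", "seedlings.csv", "physiology.csv")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7))
  }
  d3 <- allelo_design(seed = 778)
  s3 <- simulate_germination(d3, eff)
  expect_false(identical(s1$dishes$n7, s3$dishes$n7))
})

test_that("generated data do not depend on group iteration order", {
  eff <- list(CK = treatment_effect(0.8), A = treatment_effect(0.9),
              B = treatment_effect(0.7))
  d_ab <- allelo_design(treatments = c("A", "B"), seed = 5)
  sim <- simulate_germination(d_ab, eff)
  # dropping B leaves A's dishes unchanged: per-(group, dish) substreams
  d_a <- allelo_design(treatments = "A", seed = 5)
  sim_a <- simulate_germination(d_a, eff[c("CK", "A")])
  expect_identical(sim$dishes[sim$dishes$treatment == "A", "n7"],
                   sim_a$dishes[sim_a$dishes$treatment == "A", "n7"])
})

test_that("noise-free physiology reproduces control means and multipliers", {
  d <- allelo_design(treatments = "T1", seed = 4)
  eff <- list(
    CK = treatment_effect(0.8, physio_cv = 0,
                          physio_multipliers = c(MDA = 1, SOD = 1)),
    T1 = treatment_effect(0.8, physio_cv = 0,
                          physio_multipliers = c(MDA = 2, SOD = 1)))
  ph <- simulate_physiology(d, eff, control_means = c(MDA = 8, SOD = 180))
  ck_mda <- ph$value[ph$treatment == "CK" & ph$indicator == "MDA"]
  t1_mda <- ph$value[ph$treatment == "T1" & ph$indicator == "MDA"]
  expect_equal(ck_mda, rep(8, 12))
  expect_equal(t1_mda, rep(16, 12))
  expect_equal(ph$value[ph$treatment == "T1" & ph$indicator == "SOD"],
               rep(180, 12))
  expect_error(simulate_physiology(d, eff, control_means = c(MDA = 8)),
               "missing from control_means")
})

test_that("physiology grand-mean ratio converges to the planted multiplier", {
  # 500 datasets, multiplier 1.5, cv 0.1, 4 x 3 replication
  eff <- list(
    CK = treatment_effect(0.8, physio_cv = 0.1,
                          physio_multipliers = c(MDA = 1)),
    T1 = treatment_effect(0.8, physio_cv = 0.1,
                          physio_multipliers = c(MDA = 1.5)))
  ratios <- vapply(seq_len(500), function(i) {
    d <- allelo_design(treatments = "T1", seed = 2000 + i)
    ph <- simulate_physiology(d, eff, control_means = c(MDA = 8))
    mean(ph$value[ph$treatment == "T1"]) / mean(ph$value[ph$treatment == "CK"])
  }, numeric(1))
  mc_se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1.5), 3 * mc_se)
})
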