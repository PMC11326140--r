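test_that("blot normalization reproduces the ratio-of-ratios arithmetic", {
  out <- normalize_blots(rbind(c(100, 300), c(100, 300)),
                         rbind(c(50, 75), c(50, 75)),
                         time_grid = c(0, 5))
  expect_equal(unname(out$values), rbind(c(1, 2), c(1, 2)))

  # identical raw and loading signals give flat fold changes
  x <- matrix(runif(18, 10, 100), 2, 9)
  flat <- normalize_blots(x, x, grid9)
  expect_true(all(flat$values == 1))

  # scale invariance: rescaling all raw signals leaves the output unchanged
  set.seed(1)
  raw <- matrix(runif(27, 50, 500), 3, 9)
  load <- matrix(runif(27, 50, 500), 3, 9)
  expect_equal(normalize_blots(raw, load, grid9)$values,
               normalize_blots(raw * 7.3, load, grid9)$values)

  # spreadsheet-style oracle on random positive series with background
  bg <- 5
  expected <- ((raw - bg) / (load - bg)) /
    ((raw[, 1] - bg) / (load[, 1] - bg))
  got <- normalize_blots(raw, load, grid9, background = bg)
  expect_equal(unname(got$values), unname(expected), tolerance = 1e-12)

  # non-positive background-corrected signal names the band
  bad <- raw; bad[2, 3] <- 2
  expect_error(normalize_blots(bad, load, grid9, protein = "AKT1",
                               background = 5),
               "AKT1.*replicate 2.*15 min", class = "phosnet_data_error")
})

test_that("the paired t-test matches its closed form and conventions", {
  # worked example: d = (0.1, 0.2, 0.3)
  p <- paired_ttest(c(1.1, 1.2, 1.3), c(1.0, 1.0, 1.0))
  expect_equal(attr(p, "statistic"), 3.4641, tolerance = 1e-4)
  expect_equal(as.numeric(p), 0.0742, tolerance = 1e-3)

  # identical vectors: p = 1 by convention, flagged
  p1 <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.numeric(p1), 1)
  expect_identical(attr(p1, "flag"), "zero_diff")

  # zero spread around a nonzero mean difference: p = 0, flagged
  p0 <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(as.numeric(p0), 0)
  expect_identical(attr(p0, "flag"), "zero_sd")

  expect_error(paired_ttest(1, c(1, 2)), class = "phosnet_data_error")
})

test_that("the paired t-test agrees with the reference implementation", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (sd(x - y) == 0) next
    expect_equal(as.numeric(paired_ttest(x, y)),
                 t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("significance scores have the right shape and flat series are null", {
  flat <- phospho_timeseries("x", grid9, matrix(1, 3, 9))
  sc <- compute_significance(flat)
  expect_length(sc$firstscores, 8)
  expect_length(sc$prevscores, 8)
  expect_true(all(sc$firstscores == 1) && all(sc$prevscores == 1))
  expect_true(all(c(sc$firstscores, sc$prevscores) >= 0 &
                    c(sc$firstscores, sc$prevscores) <= 1))
})

test_that("a realistic step is detected at nearly every seed", {
  detected <- 0L
  for (s in 1:200) {
    set.seed(s)
    mu <- ifelse(grid9 >= 15, 2, 1)
    v <- t(replicate(3, mu * phosnet:::lnorm_noise(9, 0.05)))
    v[, 1] <- 1
    sc <- compute_significance(phospho_timeseries("x", grid9, v))
    post <- grid9[-1] >= 15
    detected <- detected + all(sc$firstscores[post] < 0.05)
  }
  expect_gte(detected, 180)
})

test_that("activity discretization follows the sign-and-threshold rule", {
  # significant increase at 5 min onward
  up <- phospho_timeseries("up", grid9,
                           rbind(ifelse(grid9 >= 5, 1.8, 1),
                                 ifelse(grid9 >= 5, 1.82, 1),
                                 ifelse(grid9 >= 5, 1.78, 1)))
  pr <- discretize_activity(up, compute_significance(up))
  expect_identical(unname(pr$states[1]), "inactive")
  expect_true(all(pr$states[-1] == "activated"))

  # non-significant wobble stays inactive
  set.seed(8)
  wm <- rbind(1 + c(0, rnorm(8, 0, 0.3)),
              1 + c(0, rnorm(8, 0, 0.3)),
              1 + c(0, rnorm(8, 0, 0.35)))
  wm <- pmax(wm, 0.05); wm[, 1] <- 1
  wob <- phospho_timeseries("w", grid9, wm)
  prw <- discretize_activity(wob, compute_significance(wob))
  sc <- compute_significance(wob)
  nonsig <- pmin(sc$firstscores, sc$prevscores) > 0.05
  expect_true(all(prw$states[-1][nonsig] == "inactive"))

  # planted noiseless inhibition is called inhibited at and after onset
  dn <- phospho_timeseries("dn", grid9,
                           matrix(rep(ifelse(grid9 >= 30, 0.5, 1), each = 3),
                                  3, 9))
  prd <- discretize_activity(dn, compute_significance(dn))
  expect_true(all(prd$states[grid9 >= 30] == "inhibited"))
  expect_true(all(prd$states[grid9 < 30] == "inactive"))
})

test_that("prizes are the capped negative log of the best p-value and monotone", {
  mk <- function(fs, ps) {
    structure(list(protein = "x", firstscores = fs, prevscores = ps,
                   threshold = 0.05), class = "significance_scores")
  }
  expect_equal(unname(compute_prizes(mk(c(0.01, 0.5), c(0.9, 0.9)))), 2)
  expect_equal(unname(compute_prizes(mk(rep(1, 8), rep(1, 8)))), 0)
  expect_equal(unname(compute_prizes(mk(c(0, 0.5), c(0.9, 0.9)))), 10)

  # lowering any p-value never lowers the prize
  set.seed(21)
  for (i in 1:50) {
    fs <- runif(8); ps <- runif(8)
    base <- compute_prizes(mk(fs, ps))
    j <- sample(8, 1)
    fs2 <- fs; fs2[j] <- fs[j] * runif(1)
    expect_gte(unname(compute_prizes(mk(fs2, ps))), unname(base))
  }
})

test_that("noiseless preprocessing recovers planted activation times exactly", {
  cfg <- sim_config(noise_cv = 0, seed = 5)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  ds <- generate_timeseries(truth, net, cfg)
  prep <- preprocess_dataset(ds)
  fc <- first_changes(prep$profiles)
  for (p in setdiff(names(truth$activation_times), truth$source_node)) {
    expect_equal(fc$first_change[fc$protein == p],
                 unname(truth$activation_times[[p]]))
    expect_equal(fc$direction[fc$protein == p],
                 unname(truth$cum_sign[[p]]))
  }
  # unresponsive bystanders never change
  bystanders <- setdiff(names(ds), names(truth$activation_times))
  expect_true(all(fc$first_change[fc$protein %in% bystanders] == Inf))
})
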