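test_that("candidate enumeration honors partial-model restrictions", {
  sub <- make_sub("A-B", source = "A")
  # no prior: both orientations, both signs
  expect_equal(nrow(candidate_events(sub, NULL)), 4)
  # signed prior pins direction and sign
  c1 <- candidate_events(sub, make_pm("A", "B", 1L))
  expect_equal(nrow(c1), 1)
  expect_identical(c1$from, "A"); expect_equal(c1$sign, 1L)
  # unsigned prior pins direction only
  c2 <- candidate_events(sub, make_pm("A", "B", NA_integer_))
  expect_equal(nrow(c2), 2)
  expect_true(all(c2$from == "A"))
  # priors in both directions leave both orientations open
  c3 <- candidate_events(sub, make_pm(c("A", "B"), c("B", "A"),
                                      c(NA_integer_, NA_integer_)))
  expect_equal(nrow(c3), 4)
})

test_that("path validity encodes timing, terminal and sign-product rules", {
  profiles <- list(A = step_profile("A", 5), B = step_profile("B", 15))
  # activation at 5 min downstream of an activating edge: valid
  expect_true(is_valid_path(c("S", "A"), 1L, profiles, "S"))
  # first-change times must be non-decreasing
  expect_false(is_valid_path(c("S", "B", "A"), c(1L, 1L), profiles, "S"))
  expect_true(is_valid_path(c("S", "A", "B"), c(1L, 1L), profiles, "S"))
  # an inhibitory edge cannot explain an activation
  expect_false(is_valid_path(c("S", "A"), -1L, profiles, "S"))
  # ... but a double negative can
  inh <- list(A = step_profile("A", 5, "inhibited"),
              B = step_profile("B", 15))
  expect_true(is_valid_path(c("S", "A"), -1L, inh, "S"))
  expect_true(is_valid_path(c("S", "A", "B"), c(-1L, -1L), inh, "S"))
  # terminal node must be measured and changing
  expect_false(is_valid_path(c("S", "A", "X"), c(1L, 1L), profiles, "S"))
  flat <- list(A = flat_profile("A"))
  expect_false(is_valid_path(c("S", "A"), 1L, flat, "S"))
  expect_error(is_valid_path(c("A", "B"), 1L, profiles, "S"),
               class = "phosnet_data_error")
})

test_that("a directed signed chain is synthesized fully signed", {
  sub <- make_sub("S-A A-B")
  pm <- make_pm(c("S", "A"), c("A", "B"), c(1L, 1L))
  profiles <- list(A = step_profile("A", 5), B = step_profile("B", 15))
  syn <- synthesize(sub, pm, profiles, "S")
  expect_equal(summary_df(syn$summary),
               data.frame(from = c("A", "S"), to = c("B", "A"),
                          sign = "activation", n_paths = c(1L, 2L),
                          stringsAsFactors = FALSE))
  # matches the exhaustive oracle
  expect_equal(summary_df(brute_force_summary(sub, pm, profiles, "S")),
               summary_df(syn$summary))
})

test_that("ambiguous orientations are emitted both ways, unsigned", {
  sub <- make_sub("S-A S-B A-B")
  profiles <- list(A = step_profile("A", 5), B = step_profile("B", 5))
  syn <- synthesize(sub, NULL, profiles, "S")
  d <- summary_df(syn$summary)
  expect_true(all(c("A B", "B A") %in% paste(d$from, d$to)))
  expect_true(all(d$sign[d$from %in% c("A", "B") &
                           d$to %in% c("A", "B")] == "unknown"))
  expect_equal(summary_df(brute_force_summary(sub, NULL, profiles, "S")), d)
})

test_that("synthesis is empty (with diagnostics) when nothing changes", {
  sub <- make_sub("S-A")
  syn <- synthesize(sub, NULL, list(A = flat_profile("A")), "S")
  expect_equal(nrow(syn$summary), 0)
  # changing nodes that no valid path reaches are reported
  pm_block <- make_pm("A", "S", 1L)  # only A -> S orientation allowed
  syn2 <- synthesize(sub, pm_block, list(A = step_profile("A", 5)), "S")
  expect_equal(nrow(syn2$summary), 0)
  expect_identical(attr(syn2$summary, "unexplained"), "A")
})

test_that("pruned search equals exhaustive enumeration on random instances", {
  for (seed in 1:30) {
    inst <- random_instance(seed, n_nodes = sample(5:9, 1))
    syn <- synthesize(inst$sub, inst$pm, inst$profiles, "S",
                      max_path_len = 11)
    oracle <- brute_force_summary(inst$sub, inst$pm, inst$profiles, "S")
    expect_equal(summary_df(syn$summary), summary_df(oracle),
                 info = paste("seed", seed))
  }
})

test_that("the exhaustive oracle enforces its size limit and degenerate input", {
  big <- subnetwork(data.frame(from = paste0("n", 1:13),
                               to = paste0("n", 2:14)), "n1")
  expect_error(brute_force_summary(big, NULL, list(), "n1"),
               class = "phosnet_config_error")
  lone <- subnetwork(data.frame(from = character(0), to = character(0)), "S")
  expect_equal(nrow(brute_force_summary(lone, NULL, list(), "S")), 0)
})

test_that("dropping the partial model never removes directed edges", {
  for (seed in 1:15) {
    inst <- random_instance(seed)
    if (is.null(inst$pm)) next
    with_pm <- synthesize(inst$sub, inst$pm, inst$profiles, "S",
                          max_path_len = 11)$summary
    without <- synthesize(inst$sub, NULL, inst$profiles, "S",
                          max_path_len = 11)$summary
    expect_true(all(paste(with_pm$from, with_pm$to) %in%
                      paste(without$from, without$to)))
    # signed edges are a subset of directed edges by construction
    expect_true(all(with_pm$sign %in% c("activation", "inhibition",
                                        "unknown")))
  }
})

test_that("sign resolution degrades as measurement coverage shrinks", {
  # with fewer measured nodes, fewer summary edges can be pinned to a sign
  signed_fraction <- function(frac, seeds) {
    vals <- vapply(seeds, function(seed) {
      set.seed(seed)
      inst <- random_instance(seed, n_nodes = 8)
      keep <- names(inst$profiles)[
        seq_len(max(1, round(frac * length(inst$profiles))))]
      syn <- synthesize(inst$sub, inst$pm, inst$profiles[keep], "S",
                        max_path_len = 11)$summary
      if (nrow(syn) == 0) return(NA_real_)
      mean(syn$sign != "unknown")
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  expect_gte(signed_fraction(1, 1:50) + 0.02, signed_fraction(0.4, 1:50))
})

test_that("a noiseless planted cascade is recovered exactly end to end", {
  cfg <- sim_config(noise_cv = 0, seed = 12)
  rep <- run_pipeline(cfg)
  expect_equal(rep$recovery$recall, 1)
  expect_equal(rep$recovery$sign_errors, 0)
  # every summary edge lies on at least one valid path (provenance counts)
  expect_true(all(rep$summary$n_paths >= 1))
  # activity windows: measured nodes match their profiles; source active at 0
  w <- rep$windows
  expect_true(w$states[[rep$truth$source_node]][1, "activated"])
  expect_false(any(w$states[[rep$truth$source_node]][1, c("inhibited",
                                                          "inactive")]))
  p1 <- names(rep$preprocessing$profiles)[1]
  states <- rep$preprocessing$profiles[[p1]]$states
  if (p1 %in% names(w$states)) {
    m <- w$states[[p1]]
    expect_true(all(m[cbind(seq_along(states),
                            match(states, colnames(m)))]))
  }
})
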