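test_that("generators are byte-deterministic for a fixed seed and config", {
  cfg <- sim_config(n_proteins = 30, n_kinases = 12, cascade_size = 8,
                    n_measured = 14, seed = 11)
  a <- generate_interactome(cfg); b <- generate_interactome(cfg)
  expect_identical(a, b)
  ta <- plant_cascade(a, cfg); tb <- plant_cascade(b, cfg)
  expect_identical(ta, tb)
  da <- generate_timeseries(ta, a, cfg); db <- generate_timeseries(tb, b, cfg)
  expect_identical(da, db)
  ma <- generate_inhibition_matrix(ta, a, cfg)
  expect_identical(ma, generate_inhibition_matrix(tb, b, cfg))
  expect_identical(generate_permeability_screen(ta, ma, cfg),
                   generate_permeability_screen(tb, ma, cfg))
  expect_identical(generate_treking_fixture(ta, a, cfg),
                   generate_treking_fixture(tb, b, cfg))
})

test_that("interactome construction rules hold and PPI layer is connected", {
  cfg <- sim_config(n_proteins = 50, n_kinases = 20, cascade_size = 10,
                    n_measured = 20, seed = 7)
  net <- generate_interactome(cfg)
  kin <- net$nodes$id[net$nodes$is_kinase]
  expect_true(all(net$ks$kinase %in% kin))
  expect_true(all(net$ppi$confidence > 0 & net$ppi$confidence <= 1))
  expect_false(any(net$ppi$from == net$ppi$to))
  # connectivity verified by an independent graph-search oracle
  g <- igraph::graph_from_data_frame(net$ppi, directed = FALSE,
                                     vertices = net$nodes$id)
  expect_equal(igraph::components(g)$no, 1)
  # invalid counts rejected
  expect_error(sim_config(n_proteins = 5, n_kinases = 8),
               class = "phosnet_config_error")
})

test_that("planted cascades are source-rooted DAGs over interactome edges", {
  for (seed in c(1, 5, 9)) {
    cfg <- sim_config(seed = seed)
    net <- generate_interactome(cfg)
    truth <- plant_cascade(net, cfg)
    expect_identical(truth$source_node, net$source)
    expect_equal(unname(truth$activation_times[[truth$source_node]]), 0)
    # every cascade edge is an orientation of an existing adjacency
    adj <- c(paste(net$ppi$from, net$ppi$to), paste(net$ppi$to, net$ppi$from),
             paste(net$ks$kinase, net$ks$substrate))
    expect_true(all(paste(truth$cascade_edges$from,
                          truth$cascade_edges$to) %in% adj))
    # activation times non-decreasing along every edge, on the grid
    at <- truth$activation_times
    expect_true(all(at[truth$cascade_edges$to] >=
                      at[truth$cascade_edges$from]))
    expect_true(all(at %in% cfg$time_grid))
    # acyclic and connected: each non-source node has exactly one parent
    expect_equal(anyDuplicated(truth$cascade_edges$to), 0)
    g <- igraph::graph_from_data_frame(truth$cascade_edges)
    expect_true(igraph::is_dag(g))
  }
  expect_error(plant_cascade(interactome(
    data.frame(id = c("a", "b"), is_kinase = c(FALSE, FALSE)),
    data.frame(from = "a", to = "b", confidence = 0.9),
    data.frame(kinase = character(0), substrate = character(0),
               sign = integer(0), confidence = numeric(0))
  ), sim_config()), class = "phosnet_data_error")
})

test_that("noiseless time series follow the planted step profiles exactly", {
  cfg <- sim_config(noise_cv = 0, seed = 3)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  ds <- generate_timeseries(truth, net, cfg)
  expect_length(ds, cfg$n_measured)
  for (p in names(ds)) {
    v <- ds[[p]]$values
    expect_equal(dim(v), c(cfg$n_replicates, length(cfg$time_grid)))
    expect_true(all(v[, 1] == 1))
    if (p %in% names(truth$activation_times)) {
      at <- truth$activation_times[[p]]
      pre <- cfg$time_grid < at
      expect_true(all(v[, pre] == 1))
      if (truth$cum_sign[[p]] > 0) {
        expect_true(all(v[, !pre] == cfg$activation_amplitude))
      } else {
        expect_true(all(v[, !pre] == cfg$inhibition_amplitude))
      }
    } else {
      expect_true(all(v == 1))
    }
  }
})

test_that("replicate noise has the configured coefficient of variation", {
  set.seed(42)
  x <- phosnet:::lnorm_noise(1000, 0.2)
  expect_lt(abs(sd(x) / mean(x) - 0.2), 0.03)
  expect_identical(phosnet:::lnorm_noise(5, 0), rep(1, 5))
})

test_that("inhibition matrices are bounded and null compounds leave the screen at control level", {
  cfg <- sim_config(seed = 2)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  mat <- generate_inhibition_matrix(truth, net, cfg)
  expect_true(all(mat >= 0 & mat <= 100))
  expect_equal(dim(mat), c(cfg$n_kinases, cfg$n_compounds))
  # a compound inhibiting nothing: its AUC distribution matches DMSO
  null_mat <- mat; null_mat[] <- 100
  class(null_mat) <- class(mat)
  scr <- generate_permeability_screen(truth, null_mat, cfg)
  by_cp <- tapply(scr$auc$auc, scr$auc$compound, mean)
  expect_true(all(abs(by_cp - 1) < 5 * cfg$assay_cv))
})

test_that("planted perturbing compounds trip the permeability rule in nearly every seed", {
  cfg0 <- sim_config(seed = 1)
  net <- generate_interactome(cfg0)
  truth <- plant_cascade(net, cfg0)
  mat <- generate_inhibition_matrix(truth, net, cfg0)
  cls <- attr(mat, "compound_class")
  target <- names(cls)[cls == "barrier"][1]
  hits <- 0L
  for (s in 1:100) {
    cfg <- sim_config(seed = s)
    scr <- generate_permeability_screen(truth, mat, cfg)
    dmso <- scr$auc$auc[scr$auc$compound == "DMSO"]
    cp <- scr$auc$auc[scr$auc$compound == target]
    hits <- hits + permeability_differs(cp, dmso)
  }
  expect_gte(hits, 95)
})

test_that("an empty barrier set warns and leaves the screen unperturbed", {
  cfg <- sim_config(seed = 4)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  mat <- generate_inhibition_matrix(truth, net, cfg)
  truth$barrier_kinases <- character(0)
  expect_warning(scr <- generate_permeability_screen(truth, mat, cfg),
                 "unperturbed")
  by_cp <- tapply(scr$auc$auc, scr$auc$compound, mean)
  expect_true(all(abs(by_cp - 1) < 5 * cfg$assay_cv))
})

test_that("the functional model fixture satisfies its contracts", {
  cfg <- sim_config(seed = 6)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  trek <- generate_treking_fixture(truth, net, cfg)
  expect_true(all(trek$clusters >= 1 & trek$clusters <= cfg$n_clusters))
  expect_true(all(trek$functionality %in%
                    c("weakening", "strengthening", "both", "none")))
  # background reuses the interactome's kinase-substrate layer
  expect_identical(trek$background,
                   data.frame(from = net$ks$kinase, to = net$ks$substrate,
                              stringsAsFactors = FALSE))
  # barrier kinases are functional in windows overlapping their activation
  for (k in truth$barrier_kinases) {
    iv <- trek$intervals[[k]]
    at <- truth$activation_times[[k]]
    expect_true(any(iv[, "start"] <= at & iv[, "end"] >= at))
  }
})
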