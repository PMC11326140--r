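test_that("node shuffling is a pure relabeling", {
  set.seed(51)
  edges <- data.frame(from = sample(letters[1:8], 15, TRUE),
                      to = sample(letters[1:8], 15, TRUE),
                      stringsAsFactors = FALSE)
  edges <- unique(edges[edges$from != edges$to, ])
  shuf <- shuffle_network_nodes(edges, seed = 2)
  expect_equal(nrow(shuf), nrow(edges))
  deg <- function(e) sort(unname(table(c(e$from, e$to))))
  expect_equal(deg(shuf), deg(edges))
  # in/out degree multisets preserved for directed interpretation
  expect_equal(sort(unname(table(factor(shuf$from)))),
               sort(unname(table(factor(edges$from)))))
  # identity permutation reproduces the input
  ids <- sort(unique(c(edges$from, edges$to)))
  idp <- stats::setNames(ids, ids)
  expect_equal(shuffle_network_nodes(edges, perm = idp), edges)
  expect_error(shuffle_network_nodes(edges[0, ]),
               class = "phosnet_data_error")
})

test_that("value shuffling preserves multisets and shapes", {
  cfg <- sim_config(n_proteins = 30, n_kinases = 12, cascade_size = 6,
                    n_measured = 10, seed = 8)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  ds <- generate_timeseries(truth, net, cfg)
  prep <- preprocess_dataset(ds)
  shf <- shuffle_timeseries(ds, prep$scores, seed = 3)
  vals <- function(d) sort(unname(unlist(lapply(d, function(ts) ts$values))))
  expect_equal(vals(shf$dataset), vals(ds))
  expect_equal(lapply(shf$dataset, function(ts) dim(ts$values)),
               lapply(ds, function(ts) dim(ts$values)))
  sc_vals <- function(s, f) sort(unname(unlist(lapply(s, `[[`, f))))
  expect_equal(sc_vals(shf$scores, "firstscores"),
               sc_vals(prep$scores, "firstscores"))
  expect_equal(sc_vals(shf$scores, "prevscores"),
               sc_vals(prep$scores, "prevscores"))
  # distinct seeds give distinct permutations (collision check)
  differs <- 0
  for (i in 1:20) {
    a <- shuffle_timeseries(ds, prep$scores, seed = 100 + i)$dataset
    b <- shuffle_timeseries(ds, prep$scores, seed = 200 + i)$dataset
    differs <- differs + !identical(a, b)
  }
  expect_equal(differs, 20)
  # per-protein granularity preserves each protein's own value pool
  pp <- shuffle_timeseries(ds, prep$scores, seed = 4,
                           granularity = "per_protein")
  for (p in names(ds)) {
    expect_equal(sort(as.vector(pp$dataset[[p]]$values)), sort(as.vector(ds[[p]]$values)))
  }
})

test_that("the configuration model preserves degree sequences exactly pre-collapse", {
  set.seed(61)
  for (i in 1:5) {
    ids <- paste0("n", 1:12)
    edges <- unique(data.frame(from = sample(ids, 30, TRUE),
                               to = sample(ids, 30, TRUE),
                               stringsAsFactors = FALSE))
    edges <- edges[edges$from != edges$to, ]
    out <- configuration_model_network(edges, seed = i)
    multi <- attr(out, "multigraph")
    degtab <- function(e, col) table(factor(e[[col]], levels = ids))
    expect_equal(degtab(multi, "from"), degtab(edges, "from"))
    expect_equal(degtab(multi, "to"), degtab(edges, "to"))
    # collapsed output has no loops or duplicates
    expect_false(any(out$from == out$to))
    expect_equal(anyDuplicated(paste(out$from, out$to)), 0)
  }
  # a single-edge graph can only be itself
  one <- data.frame(from = "a", to = "b", stringsAsFactors = FALSE)
  expect_equal(configuration_model_network(one, seed = 1), one,
               ignore_attr = TRUE)
})

test_that("configuration-model randomization actually moves edges", {
  set.seed(71)
  ids <- paste0("n", 1:100)
  edges <- unique(data.frame(from = sample(ids, 300, TRUE),
                             to = sample(ids, 300, TRUE),
                             stringsAsFactors = FALSE))
  edges <- edges[edges$from != edges$to, ]
  key <- paste(edges$from, edges$to)
  overlap <- vapply(1:20, function(s) {
    r <- configuration_model_network(edges, seed = s)
    mean(paste(r$from, r$to) %in% key)
  }, numeric(1))
  expect_lt(mean(overlap), 0.5)
})

test_that("random functional models match the true model's selection rates", {
  cfg <- sim_config(seed = 9)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  trek <- generate_treking_fixture(truth, net, cfg)
  ncfg <- treking_null_config(n_kir_kinases = length(trek$kinases),
                              n_clusters = cfg$n_clusters)
  true_weak <- colSums(trek$functionality == "weakening" |
                         trek$functionality == "both")
  counts <- matrix(0, 50, length(trek$time_grid))
  for (s in 1:50) {
    m <- random_treking_model(ncfg, trek, seed = 1000 + s)
    counts[s, ] <- colSums(m$functionality == "weakening" |
                             m$functionality == "both")
    expect_true(all(m$clusters >= 1 & m$clusters <= ncfg$n_clusters))
  }
  # mean selected count per time point within 3 binomial SDs of the target
  n <- length(trek$kinases)
  for (j in seq_along(trek$time_grid)) {
    p <- true_weak[j] / n
    tol <- 3 * sqrt(p * (1 - p) * n / 50) + 1e-9
    expect_lt(abs(mean(counts[, j]) - true_weak[j]), max(tol, 0.5))
  }
})

test_that("cluster networks lie on shortest paths between same-cluster kinases", {
  cfg <- sim_config(seed = 10)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  trek <- generate_treking_fixture(truth, net, cfg)
  # few clusters so that same-cluster pairs (and hence path networks) exist
  m <- random_treking_model(treking_null_config(30, 4), trek, seed = 77)
  g <- igraph::graph_from_data_frame(m$background, directed = TRUE)
  d <- igraph::distances(g, mode = "out")
  sel <- m$kinases[apply(m$functionality != "none", 1, any)]
  n_edges <- sum(vapply(m$cluster_networks, nrow, 1L))
  expect_gt(n_edges, 0)
  for (cl in names(m$cluster_networks)) {
    en <- m$cluster_networks[[cl]]
    members <- intersect(sel[m$clusters[sel] == as.integer(cl)],
                         rownames(d))
    for (i in seq_len(nrow(en))) {
      u <- en$from[i]; v <- en$to[i]
      on_path <- any(vapply(members, function(a) {
        any(vapply(members, function(b) {
          a != b && is.finite(d[a, b]) &&
            isTRUE(abs(d[a, u] + 1 + d[v, b] - d[a, b]) < 1e-9)
        }, logical(1)))
      }, logical(1)))
      expect_true(on_path, info = paste("cluster", cl, u, "->", v))
    }
  }
})

test_that("null ensembles are sized, bounded and reproducible", {
  cfg <- sim_config(seed = 13)
  net <- generate_interactome(cfg)
  truth <- plant_cascade(net, cfg)
  ds <- generate_timeseries(truth, net, cfg)
  trek <- generate_treking_fixture(truth, net, cfg)
  ncfg <- treking_null_config(n_kir_kinases = length(trek$kinases),
                              n_clusters = cfg$n_clusters)
  e1 <- random_treking_ensemble(ncfg, trek, ds, n = 10, base_seed = 5)
  e2 <- random_treking_ensemble(ncfg, trek, ds, n = 10, base_seed = 5)
  expect_identical(e1, e2)
  expect_equal(e1$n_iterations, 10)
  ok <- e1$accuracies[!is.na(e1$accuracies)]
  expect_true(all(ok >= 0 & ok <= 100))
  s <- summarize_null(e1, true_accuracy = 100)
  expect_equal(s$n_iterations, 10)
  expect_true(s$empirical_p >= 0 && s$empirical_p <= 1)
})
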