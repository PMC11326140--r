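# in-code fixtures shared across the suite

grid9 <- phospho_time_grid()

# an activity profile with prescribed states (length = grid)
make_profile <- function(protein, states, tg = grid9) {
  structure(list(protein = protein, time_grid = tg,
                 states = stats::setNames(states, paste0("t", tg))),
            class = "activity_profile")
}

# profile that first changes at `at` minutes with the given direction and
# stays changed (sustained step semantics)
step_profile <- function(protein, at, direction = "activated", tg = grid9) {
  states <- ifelse(tg >= at & tg > 0, direction, "inactive")
  make_profile(protein, states, tg)
}

flat_profile <- function(protein, tg = grid9) {
  make_profile(protein, rep("inactive", length(tg)), tg)
}

# small undirected subnetwork from an edge string like "S-A A-B"
make_sub <- function(edge_str, source = "S") {
  pairs <- strsplit(strsplit(edge_str, " ")[[1]], "-")
  subnetwork(data.frame(from = vapply(pairs, `[`, "", 1),
                        to = vapply(pairs, `[`, "", 2),
                        stringsAsFactors = FALSE), source)
}

make_pm <- function(from = character(0), to = character(0),
                    sign = integer(0)) {
  partial_model(data.frame(from = from, to = to, sign = sign,
                           stringsAsFactors = FALSE))
}

# random small synthesis instance for oracle-equivalence checks: a connected
# undirected graph, a sprinkling of measured nodes with random first-change
# behavior, and a random partial model over the same nodes
random_instance <- function(seed, n_nodes = 8, n_edges = 10) {
  set.seed(seed)
  ids <- c("S", paste0("N", seq_len(n_nodes - 1)))
  from <- character(0); to <- character(0)
  for (i in 2:n_nodes) {            # spanning tree first
    from <- c(from, ids[sample.int(i - 1, 1)]); to <- c(to, ids[i])
  }
  extra <- n_edges - (n_nodes - 1)
  seen <- paste(pmin(from, to), pmax(from, to))
  while (extra > 0) {
    uv <- sample(ids, 2)
    key <- paste(min(uv), max(uv))
    if (!key %in% seen) {
      from <- c(from, uv[1]); to <- c(to, uv[2])
      seen <- c(seen, key); extra <- extra - 1
    }
  }
  sub <- subnetwork(data.frame(from = from, to = to,
                               stringsAsFactors = FALSE), "S")
  measured <- sample(ids[-1], max(2, rbinom(1, n_nodes - 1, 0.6)))
  tg <- grid9
  profiles <- lapply(measured, function(p) {
    if (runif(1) < 0.2) return(flat_profile(p))
    step_profile(p, sample(tg[-1], 1),
                 sample(c("activated", "inhibited"), 1))
  })
  names(profiles) <- measured
  n_pm <- rbinom(1, n_edges, 0.4)
  pm <- if (n_pm > 0) {
    idx <- sample(length(from), n_pm)
    dirswap <- runif(n_pm) < 0.5
    make_pm(ifelse(dirswap, to[idx], from[idx]),
            ifelse(dirswap, from[idx], to[idx]),
            sample(c(1L, -1L, NA_integer_), n_pm, replace = TRUE))
  } else NULL
  list(sub = sub, pm = pm, profiles = profiles)
}

# summary networks as comparable sorted data.frames
summary_df <- function(s) {
  d <- as.data.frame(s)[c("from", "to", "sign", "n_paths")]
  d <- d[order(d$from, d$to), ]
  rownames(d) <- NULL
  d
}
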