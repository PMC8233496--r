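# Independent oracles and fixture builders used across the suite.

# Site-by-site log-likelihood: evaluates every column as its own one-site
# alignment, bypassing pattern compression entirely.
uncompressed_loglik <- function(phy, aln, model) {
  sum(vapply(seq_len(ncol(aln)), function(j) {
    log_likelihood(phy, compress_patterns(aln[, j, drop = FALSE],
      alphabet = attr(aln, "alphabet")), model)
  }, numeric(1)))
}

# Brute-force joint likelihood by exhaustive summation over all internal
# node states (and the focal tip, when marginalizing); independent of the
# pruning code path. Single rate category only.
brute_force_site_lik <- function(phy, tip_states, model) {
  ix <- chronotree:::.tree_index(phy)
  s <- length(model$states)
  internals <- (ix$n_tip + 1):ix$n_all
  Ps <- lapply(seq_len(ix$n_all), function(v) {
    if (v == ix$root) NULL else transition_matrix(model, ix$blen[v])
  })
  grid <- expand.grid(rep(list(seq_len(s)), length(internals)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- integer(ix$n_all)
    assign_state[internals] <- as.integer(grid[g, ])
    p <- model$freqs[assign_state[ix$root]]
    for (v in seq_len(ix$n_all)) {
      if (v == ix$root) next
      sv <- if (v <= ix$n_tip) tip_states[ix$tip_label[v]] else
        assign_state[v]
      if (is.na(sv)) next # missing tip: sum over states = row sum = 1
      p <- p * Ps[[v]][assign_state[ix$parent[v]], sv]
    }
    total <- total + p
  }
  total
}

# Brute-force focal-tip posterior: P(focal = a | rest) over all states.
brute_force_ep <- function(phy, tip_states, model, focal) {
  s <- length(model$states)
  joint <- vapply(seq_len(s), function(a) {
    ts <- tip_states
    ts[focal] <- a
    brute_force_site_lik(phy, ts, model)
  }, numeric(1))
  joint / sum(joint)
}

# Random test alignment with optional gaps, on a random phylogram.
random_alignment_case <- function(seed) {
  set.seed(seed)
  n_tip <- sample(4:12, 1)
  L <- sample(10:200, 1)
  tt <- simulate_timetree(n_tip, 1, seed = seed + 1)
  ph <- apply_rate_model(tt, "lognormal",
    mu = stats::runif(1, 0.05, 0.4),
    sdlog = 0.4, seed = seed + 2
  )
  model <- if (seed %% 2 == 0) {
    substitution_model("JC")
  } else {
    f <- stats::runif(4, 0.5, 1.5)
    substitution_model("HKY", freqs = f / sum(f),
      kappa = stats::runif(1, 1, 6))
  }
  aln <- simulate_alignment(ph, model, L, seed = seed + 3)
  # sprinkle missing data
  n_gap <- ceiling(0.02 * length(aln))
  aln[sample(length(aln), n_gap)] <- sample(c("-", "N", "?"), n_gap,
    replace = TRUE)
  attr(aln, "alphabet") <- "nt"
  list(tree = ph, aln = aln, model = model)
}

# First tip label under each of a node's first/last child, as a stable pair.
span_pair <- function(ix, v) chronotree:::.span_taxa(ix, v)

# Two tips on opposite sides of the root (to address the root as an MRCA).
root_spanning_tips <- function(rt) {
  ch <- rt$ix$children[[rt$ix$root]]
  tipof <- function(v) {
    while (v > rt$ix$n_tip) v <- rt$ix$children[[v]][1]
    rt$ix$tip_label[v]
  }
  c(tipof(ch[1]), tipof(ch[2]))
}
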