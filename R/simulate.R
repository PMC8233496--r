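# Synthetic-data generators: Yule timetrees, branch-rate models, serial
# tip sampling and sequence evolution. Every generator takes a mandatory
# seed and is bit-reproducible under it; true parameters are returned next
# to the data so downstream methods always have a recovery target.

#' Simulate an ultrametric timetree under a Yule (pure-birth) process
#'
#' @param n_tips number of tips (>= 2).
#' @param birth speciation rate per lineage per time unit.
#' @param seed integer seed (mandatory).
#' @param root_age optional: rescale the tree so the root sits at this age.
#' @return a `phylo` with branch lengths in time units and an `age`
#'   component (true age of every node; tips at 0).
#' @export
#' @examples
#' tt <- simulate_timetree(10, birth = 1, seed = 42)
simulate_timetree <- function(n_tips, birth = 1, seed, root_age = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth <= 0) stop("birth must be > 0")
  set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = birth, death = 0)
  ix <- .tree_index(phy)
  depth <- .node_depths(ix, ix$blen)
  age <- max(depth) - depth
  age[seq_len(ix$n_tip)] <- 0 # rphylo trees are ultrametric; fix rounding
  if (!is.null(root_age)) {
    k <- root_age / age[ix$root]
    phy$edge.length <- phy$edge.length * k
    age <- age * k
  }
  phy$age <- age
  phy
}

#' Turn a timetree into a phylogram under a branch-rate model
#'
#' Branch lengths become duration times rate. Rate models:
#' `strict` — every branch evolves at `mu`;
#' `lognormal` — independent lognormal rates, median `mu`, log-sd `sdlog`;
#' `autocorrelated` — geometric Brownian inheritance: a child branch's
#' log-rate is its parent's plus Normal(0, `step_sdlog`) noise (root
#' lineages start at `log(mu)`).
#'
#' @param timetree a `phylo` from [simulate_timetree()] (or any tree whose
#'   branch lengths are durations).
#' @param rate_model `"strict"`, `"lognormal"` or `"autocorrelated"`.
#' @param mu base rate, substitutions/site per time unit (> 0).
#' @param sdlog log-sd of independent lognormal rates.
#' @param step_sdlog per-branch log-sd of the autocorrelated walk.
#' @param seed integer seed (mandatory for the stochastic models).
#' @return a `phylo` whose branch lengths are substitutions/site, with
#'   components `rate` (true per-branch rate, indexed by node) and `age`
#'   (carried over when present).
#' @export
apply_rate_model <- function(timetree,
                             rate_model = c("strict", "lognormal",
                                            "autocorrelated"),
                             mu = 0.01, sdlog = 0.3, step_sdlog = 0.1,
                             seed = NULL) {
  rate_model <- match.arg(rate_model)
  if (mu <= 0) stop("mu must be > 0")
  if (rate_model != "strict") {
    if (is.null(seed)) stop("seed is mandatory for stochastic rate models")
    set.seed(seed)
  }
  ix <- .tree_index(timetree)
  n <- ix$n_all
  nonroot <- setdiff(seq_len(n), ix$root)
  rate <- rep(NA_real_, n)
  if (rate_model == "strict") {
    rate[nonroot] <- mu
  } else if (rate_model == "lognormal") {
    if (sdlog < 0) stop("sdlog must be >= 0")
    rate[nonroot] <- exp(log(mu) + stats::rnorm(length(nonroot), 0, sdlog))
  } else {
    if (step_sdlog < 0) stop("step_sdlog must be >= 0")
    lograte <- rep(NA_real_, n)
    lograte[ix$root] <- log(mu)
    for (v in ix$node_pre) {
      for (ch in ix$children[[v]]) {
        lograte[ch] <- lograte[v] + stats::rnorm(1, 0, step_sdlog)
      }
    }
    rate <- exp(lograte)
    rate[ix$root] <- NA_real_
  }
  out <- timetree
  out$edge.length <- (ix$blen * rate)[out$edge[, 2]]
  out$rate <- rate
  out
}

#' Serially sampled tips for tip-dating fixtures
#'
#' Cuts each terminal branch of a timetree so that tips are sampled at
#' exponentially staggered offsets before the latest date, within the
#' configured span. Offsets are Exp(3/span) draws truncated at `span` and
#' at 90% of the terminal branch duration.
#'
#' @param timetree ultrametric `phylo` with durations as branch lengths.
#' @param span sampling window in time units (> 0).
#' @param latest calendar date (decimal year) of the most recent sample.
#' @param seed integer seed (mandatory).
#' @return list with `tree` (tip branches shortened; `age` updated) and
#'   `dates` (named decimal-year sampling date per tip).
#' @export
sample_tip_dates <- function(timetree, span, latest = 2020, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (span <= 0) stop("span must be > 0")
  set.seed(seed)
  ix <- .tree_index(timetree)
  tips <- seq_len(ix$n_tip)
  offset <- pmin(stats::rexp(length(tips), rate = 3 / span), span)
  offset <- pmin(offset, 0.9 * ix$blen[tips])
  out <- timetree
  blen <- ix$blen
  blen[tips] <- blen[tips] - offset
  out$edge.length <- blen[out$edge[, 2]]
  if (!is.null(out$age)) out$age[tips] <- offset
  dates <- stats::setNames(latest - offset, ix$tip_label)
  list(tree = out, dates = dates)
}

#' Evolve a sequence alignment along a phylogram
#'
#' Root states are drawn from the model's stationary frequencies and
#' evolved branch-wise using the model's transition probabilities; with a
#' discrete-gamma model each site keeps one rate category across the whole
#' tree.
#'
#' @param phy `phylo` with branch lengths in substitutions/site.
#' @param model a `subst_model`.
#' @param L number of sites.
#' @param seed integer seed (mandatory).
#' @return character matrix (tips by sites) with attribute `alphabet`.
#' @export
simulate_alignment <- function(phy, model = substitution_model("JC"), L,
                               seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (L < 1) stop("L must be >= 1")
  set.seed(seed)
  ix <- .tree_index(phy)
  s <- length(model$states)
  ncat <- length(model$rates)
  site_cat <- if (ncat > 1) sample.int(ncat, L, replace = TRUE) else rep(1L, L)
  states <- matrix(NA_integer_, ix$n_all, L)
  states[ix$root, ] <- sample.int(s, L, replace = TRUE, prob = model$freqs)
  for (v in ix$node_pre) {
    for (ch in ix$children[[v]]) {
      for (k in unique(site_cat)) {
        cols <- which(site_cat == k)
        P <- transition_matrix(model, ix$blen[ch] * model$rates[k])
        parent_states <- states[v, cols]
        new <- integer(length(cols))
        for (ps in unique(parent_states)) {
          sel <- parent_states == ps
          new[sel] <- sample.int(s, sum(sel), replace = TRUE, prob = P[ps, ])
        }
        states[ch, cols] <- new
      }
    }
  }
  out <- matrix(model$states[states[seq_len(ix$n_tip), , drop = FALSE]],
    ix$n_tip, L,
    dimnames = list(ix$tip_label, NULL)
  )
  structure(out, alphabet = model$alphabet)
}
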