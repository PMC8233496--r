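#' Pattern-weighted phylogenetic log-likelihood
#'
#' Felsenstein pruning over the distinct site configurations of a compressed
#' alignment: the total log-likelihood is the sum of configuration
#' log-likelihoods weighted by their frequencies. Missing states (gaps,
#' ambiguity codes) contribute all-ones partials. Per-configuration scaling
#' guards against underflow; discrete-gamma models mix equiprobable rate
#' categories.
#'
#' @param phy rooted `phylo` with branch lengths (substitutions/site).
#' @param pa a `pattern_alignment` from [compress_patterns()].
#' @param model a `subst_model`; its alphabet must match `pa`.
#' @return total log-likelihood (scalar).
#' @export
log_likelihood <- function(phy, pa, model) {
  info <- .pruning_setup(phy, pa, model)
  site_log <- .pattern_loglik(info, info$ix$blen)
  sum(pa$weights * site_log)
}

# Shared setup for likelihood computations on a fixed tree/alignment/model.
.pruning_setup <- function(phy, pa, model) {
  stopifnot(inherits(pa, "pattern_alignment"), inherits(model, "subst_model"))
  if (pa$alphabet != model$alphabet) {
    stop("alignment alphabet (", pa$alphabet, ") does not match model (",
      model$alphabet, ")")
  }
  phy <- ape::collapse.singles(phy)
  .validate_tree(phy)
  missing_taxa <- setdiff(phy$tip.label, pa$taxa)
  if (length(missing_taxa)) {
    stop(
      "tree tip(s) absent from alignment: ",
      paste(missing_taxa, collapse = ", ")
    )
  }
  ix <- .tree_index(phy)
  s <- length(model$states)
  m <- pa$m
  # one-hot tip partials; missing states give all-ones columns
  tip_partial <- vector("list", ix$n_tip)
  for (v in seq_len(ix$n_tip)) {
    idx <- pa$states[match(ix$tip_label[v], pa$taxa), ]
    pt <- matrix(0, s, m)
    obs <- which(!is.na(idx))
    pt[cbind(idx[obs], obs)] <- 1
    if (length(obs) < m) pt[, setdiff(seq_len(m), obs)] <- 1
    tip_partial[[v]] <- pt
  }
  list(phy = phy, ix = ix, model = model, m = m, s = s,
       tip_partial = tip_partial, weights = pa$weights)
}

# Per-pattern log-likelihood for arbitrary branch lengths `blen` (indexed by
# node id, root entry ignored).
.pattern_loglik <- function(info, blen) {
  ix <- info$ix
  model <- info$model
  ncat <- length(model$rates)
  cat_log <- matrix(0, ncat, info$m)
  for (k in seq_len(ncat)) {
    r <- model$rates[k]
    partial <- vector("list", ix$n_all)
    partial[seq_len(ix$n_tip)] <- info$tip_partial
    logscale <- numeric(info$m)
    for (v in ix$node_po) {
      acc <- 1
      for (ch in ix$children[[v]]) {
        P <- transition_matrix(model, blen[ch] * r)
        acc <- acc * (P %*% partial[[ch]])
      }
      mx <- apply(acc, 2, max)
      mx[mx == 0] <- 1
      partial[[v]] <- acc / rep(mx, each = info$s)
      logscale <- logscale + log(mx)
    }
    cat_log[k, ] <- log(as.vector(model$freqs %*% partial[[ix$root]])) +
      logscale
  }
  # equal-weight mixture over rate categories, in log space
  top <- apply(cat_log, 2, max)
  top[!is.finite(top)] <- 0
  top + log(colMeans(exp(sweep(cat_log, 2, top)))) # log mean exp
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise scalar maximization per branch, round-robin, until the
#' largest length change falls below `tol`. The log-likelihood is
#' non-decreasing across rounds by construction.
#'
#' @param phy rooted `phylo`; input lengths are the starting point (missing
#'   or zero-length trees start from `init`).
#' @param pa a `pattern_alignment`.
#' @param model a `subst_model`.
#' @param tol convergence tolerance on branch lengths.
#' @param max_rounds maximum optimization sweeps; non-convergence warns and
#'   returns the best tree so far.
#' @param max_blen upper bound per branch (substitutions/site).
#' @param init starting length where the input has none.
#' @return `phy` with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(phy, pa, model, tol = 1e-6,
                                    max_rounds = 50, max_blen = 10,
                                    init = 0.1) {
  info <- .pruning_setup(phy, pa, model)
  ix <- info$ix
  blen <- ix$blen
  free <- setdiff(seq_len(ix$n_all), ix$root)
  if (all(blen[free] == 0)) blen[free] <- init
  obj <- function(b, v) {
    blen[v] <- b
    sum(info$weights * .pattern_loglik(info, blen))
  }
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    delta <- 0
    for (v in free) {
      opt <- stats::optimize(obj, c(0, max_blen), v = v,
        maximum = TRUE, tol = min(tol, 1e-6)
      )
      # accept only improvements (optimize can propose an interior point
      # marginally worse than a boundary optimum)
      if (opt$objective >= obj(blen[v], v)) {
        delta <- max(delta, abs(opt$maximum - blen[v]))
        blen[v] <- opt$maximum
      }
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("branch-length optimization did not converge after ",
      max_rounds, " rounds; returning best so far")
  }
  out <- info$phy
  out$edge.length <- blen[out$edge[, 2]]
  attr(out, "loglik") <- sum(info$weights * .pattern_loglik(info, blen))
  out
}
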