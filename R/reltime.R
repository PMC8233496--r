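#' Relative lineage rates and relative node times (RelTime-style)
#'
#' Estimates a relative evolutionary rate for every lineage and a relative
#' time for every node of a rooted phylogram, without assuming a molecular
#' clock. The recursion works post-order: at a node with children c1, c2 let
#' d(c) be the child's branch length plus the mean rate-adjusted node-to-tip
#' path below it; the local relative rates are r(c1) = 2 d(c1)/(d(c1)+d(c2))
#' and r(c2) = 2 d(c2)/(d(c1)+d(c2)), and a lineage's rate is the product of
#' local rates from the root. Adjusted node heights are identical through
#' either child by construction; relative times are heights normalized so
#' the root is 1 (contemporaneous tips sit at 0).
#'
#' Multifurcations are resolved as caterpillars of zero-length branches and
#' single-child chains are collapsed before the recursion; the returned
#' `tree` element is this operational tree and all node ids refer to it.
#'
#' @param phy rooted `phylo` with branch lengths (substitutions/site),
#'   at least 3 tips.
#' @param outgroup optional character vector of outgroup taxon names; their
#'   lineages get rates but are excluded from reported times.
#' @return a `reltime_result`: list with `tree`, `t_rel` (per node),
#'   `height` (adjusted heights, root = max), `rate` (per-lineage relative
#'   rate, `NA` at the root), `local_rate`, and `time_reported` (logical
#'   mask, `FALSE` for outgroup-only nodes).
#' @export
#' @examples
#' rt <- reltime(read_newick("((A:2,B:1):1,C:2);"))
#' rt$t_rel
reltime <- function(phy, outgroup = NULL) {
  phy <- .binarize(phy)
  .validate_tree(phy)
  if (length(phy$tip.label) < 3) stop("reltime needs at least 3 tips")
  if (!is.null(outgroup) && !all(outgroup %in% phy$tip.label)) {
    stop("outgroup taxa not in tree: ",
      paste(setdiff(outgroup, phy$tip.label), collapse = ", "))
  }
  ix <- .tree_index(phy)
  n <- ix$n_all
  mdepth <- numeric(n) # mean adjusted node-to-tip path, local frame
  local_rate <- rep(1, n)
  zero_subtrees <- FALSE
  for (v in ix$node_po) {
    ch <- ix$children[[v]]
    d <- ix$blen[ch] + mdepth[ch]
    if (sum(d) == 0) {
      zero_subtrees <- TRUE
      local_rate[ch] <- 1
      mdepth[v] <- 0
    } else {
      local_rate[ch] <- length(ch) * d / sum(d)
      mdepth[v] <- sum(d) / length(ch)
    }
  }
  if (zero_subtrees) {
    warning("all-zero subtree encountered; its local rates were set to 1")
  }
  rate <- rep(NA_real_, n)
  rate_floor <- 1e-9
  for (v in ix$node_pre) {
    for (ch in ix$children[[v]]) {
      up <- if (v == ix$root) 1 else rate[v]
      rate[ch] <- max(up * local_rate[ch], rate_floor)
    }
  }
  height <- numeric(n)
  height[ix$root] <- mdepth[ix$root]
  for (v in setdiff(ix$node_pre, ix$root)) {
    height[v] <- mdepth[v] / rate[v]
  }
  t_rel <- if (height[ix$root] > 0) height / height[ix$root] else height
  time_reported <- rep(TRUE, n)
  if (!is.null(outgroup) && length(outgroup)) {
    og_tips <- match(outgroup, ix$tip_label)
    in_tip <- setdiff(seq_len(ix$n_tip), og_tips)
    keep <- rep(FALSE, n)
    keep[in_tip] <- TRUE
    for (v in ix$node_po) keep[v] <- any(keep[ix$children[[v]]])
    time_reported <- keep
  }
  structure(
    list(
      tree = phy, ix = ix, t_rel = t_rel, height = height, rate = rate,
      local_rate = local_rate, mdepth = mdepth,
      time_reported = time_reported, outgroup = outgroup
    ),
    class = "reltime_result"
  )
}

#' @export
print.reltime_result <- function(x, ...) {
  cat(sprintf(
    "reltime_result: %d tips, %d nodes; root height %.6g\n",
    x$ix$n_tip, x$ix$n_all, x$height[x$ix$root]
  ))
  rr <- x$rate[!is.na(x$rate)]
  cat(sprintf(
    "  lineage rates: min %.4g, median %.4g, max %.4g\n",
    min(rr), stats::median(rr), max(rr)
  ))
  invisible(x)
}

#' Monte-Carlo samples of node times under rate perturbation
#'
#' For each replicate every lineage rate is perturbed by independent
#' lognormal noise with the given coefficient of variation (mean 1) and
#' node heights and relative times are recomputed. The resulting sample
#' matrix drives all confidence intervals downstream. With tree-only input
#' the spreads reflect rate heterogeneity only (no branch-length estimation
#' variance), so CIs are correspondingly narrower.
#'
#' @param rt a `reltime_result`.
#' @param n_samples number of replicates (>= 100).
#' @param rate_cv coefficient of variation of the multiplicative lognormal
#'   rate noise; 0 reproduces the point estimate in every replicate.
#' @param seed optional integer seed (fixed seed, identical matrix).
#' @return list with matrices `t_rel` and `height`, `n_samples` rows and
#'   one column per node of `rt$tree`.
#' @export
monte_carlo_time_samples <- function(rt, n_samples = 10000, rate_cv = 0.2,
                                     seed = NULL) {
  stopifnot(inherits(rt, "reltime_result"))
  if (n_samples < 100) stop("n_samples must be >= 100")
  if (rate_cv < 0) stop("rate_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ix <- rt$ix
  n <- ix$n_all
  nonroot <- setdiff(seq_len(n), ix$root)
  sdlog <- sqrt(log(1 + rate_cv^2))
  # adjusted branch lengths per replicate: blen / (rate * noise)
  noise <- matrix(1, n, n_samples)
  if (sdlog > 0) {
    noise[nonroot, ] <- exp(matrix(
      stats::rnorm(length(nonroot) * n_samples, -sdlog^2 / 2, sdlog),
      length(nonroot), n_samples
    ))
  }
  adj <- matrix(0, n, n_samples)
  adj[nonroot, ] <- ix$blen[nonroot] / (rt$rate[nonroot] * noise[nonroot, ])
  # heights: tip-count-weighted mean adjusted node-to-tip path
  H <- matrix(0, n, n_samples)
  for (v in ix$node_po) {
    ch <- ix$children[[v]]
    w <- ix$n_desc[ch] / ix$n_desc[v]
    acc <- 0
    for (i in seq_along(ch)) {
      acc <- acc + w[i] * (adj[ch[i], ] + H[ch[i], ])
    }
    H[v, ] <- acc
  }
  root_h <- H[ix$root, ]
  root_h[root_h == 0] <- 1
  t_rel <- sweep(t(H), 1, root_h, "/")
  list(t_rel = t_rel, height = t(H), n_samples = n_samples,
       rate_cv = rate_cv)
}
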