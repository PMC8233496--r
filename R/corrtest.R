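#' Rate-correlation features of a phylogeny
#'
#' Computes the lineage-rate correlation structure used by [corrtest()]:
#' Pearson and Spearman correlations over all (parent lineage rate, child
#' lineage rate) pairs and over all sister-lineage pairs (symmetrized by
#' including both orderings). Lineage rates come from [reltime()].
#'
#' @param phy rooted `phylo` with branch lengths (>= 10 tips), or a
#'   `reltime_result`.
#' @return named numeric vector `pc_pearson`, `pc_spearman`, `sib_pearson`,
#'   `sib_spearman`, all in \[-1, 1\].
#' @export
rate_features <- function(phy) {
  rt <- if (inherits(phy, "reltime_result")) phy else reltime(phy)
  ix <- rt$ix
  if (ix$n_tip < 10) {
    stop("rate features need at least 10 tips for stability")
  }
  rate <- rt$rate
  if (stats::sd(rate[!is.na(rate)]) < 1e-12) {
    stop("lineage rates have zero variance (strict clock); ",
      "the rate-autocorrelation test is inapplicable")
  }
  pc_parent <- numeric(0)
  pc_child <- numeric(0)
  sib_a <- numeric(0)
  sib_b <- numeric(0)
  for (v in ix$node_po) {
    ch <- ix$children[[v]]
    if (v != ix$root) {
      pc_parent <- c(pc_parent, rep(rate[v], length(ch)))
      pc_child <- c(pc_child, rate[ch])
    }
    if (length(ch) >= 2) {
      prs <- utils::combn(ch, 2)
      sib_a <- c(sib_a, rate[prs[1, ]], rate[prs[2, ]])
      sib_b <- c(sib_b, rate[prs[2, ]], rate[prs[1, ]])
    }
  }
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y, method = method)
  }
  c(
    pc_pearson = safe_cor(pc_parent, pc_child, "pearson"),
    pc_spearman = safe_cor(pc_parent, pc_child, "spearman"),
    sib_pearson = safe_cor(sib_a, sib_b, "pearson"),
    sib_spearman = safe_cor(sib_a, sib_b, "spearman")
  )
}

# logistic score from the frozen classifier (coefficients trained on the
# package's own simulator by scripts/train_corrtest.R)
.corr_score <- function(features) {
  eta <- .CORRTEST_COEF[1] + sum(.CORRTEST_COEF[-1] * features)
  stats::plogis(eta)
}

#' Test for autocorrelation of evolutionary rates (CorrTest-style)
#'
#' Maps the rate-correlation features of the phylogeny to a CorrScore in
#' \[0, 1\] with a logistic classifier trained on the package's simulator
#' (autocorrelated versus independent branch rates), and attaches an
#' empirical P-value: the fraction of independent-rate null simulations
#' (Yule topology resampled at the same tip count) whose CorrScore reaches
#' the observed one, with a +1/(n+1) correction. A high CorrScore with a
#' low P-value indicates that branch rates are inherited along lineages.
#'
#' @param phy rooted `phylo` with branch lengths (>= 10 tips).
#' @param null_reps number of null simulations (>= 100).
#' @param seed optional integer seed.
#' @param null_scores optional precomputed vector of null CorrScores for
#'   this tip count (e.g. from [corrtest_null_scores()]), reused instead of
#'   fresh simulation.
#' @param null_sdlog log-sd of the independent lognormal rates in the null.
#' @param birth Yule birth rate of the null topologies.
#' @return a `corrtest_result`: `score`, `p_value`, `features`, and null
#'   metadata (`null_reps`, `seed`, `null_sdlog`).
#' @export
corrtest <- function(phy, null_reps = 200, seed = NULL, null_scores = NULL,
                     null_sdlog = 0.3, birth = 1) {
  feats <- rate_features(phy)
  score <- .corr_score(feats)
  n_tip <- if (inherits(phy, "reltime_result")) {
    phy$ix$n_tip
  } else {
    length(phy$tip.label)
  }
  if (is.null(null_scores)) {
    if (null_reps < 100) stop("null_reps must be >= 100")
    null_scores <- corrtest_null_scores(
      n_tip, null_reps, seed = seed, null_sdlog = null_sdlog, birth = birth
    )
  }
  n <- length(null_scores)
  p <- (1 + sum(null_scores >= score)) / (n + 1)
  structure(
    list(
      score = score, p_value = p, features = feats,
      null_reps = n, seed = seed, null_sdlog = null_sdlog
    ),
    class = "corrtest_result"
  )
}

#' Null distribution of CorrScores for a given tip count
#'
#' Simulates Yule trees with independent lognormal branch rates and scores
#' each; the resulting sample can be shared across [corrtest()] calls on
#' trees of the same size.
#'
#' @param n_tip tips per null tree.
#' @param null_reps number of simulations.
#' @param seed optional integer seed.
#' @param null_sdlog log-sd of the independent rates.
#' @param birth Yule birth rate.
#' @return numeric vector of null CorrScores.
#' @export
corrtest_null_scores <- function(n_tip, null_reps, seed = NULL,
                                 null_sdlog = 0.3, birth = 1) {
  base <- if (is.null(seed)) {
    sample.int(2^30, 1)
  } else {
    as.integer(seed %% 2^30)
  }
  vapply(seq_len(null_reps), function(b) {
    tt <- simulate_timetree(n_tip, birth = birth,
      seed = (base + 2L * b) %% 2147483647L)
    ph <- apply_rate_model(tt, "lognormal", mu = 1, sdlog = null_sdlog,
      seed = (base + 2L * b + 1L) %% 2147483647L)
    .corr_score(rate_features(ph))
  }, numeric(1))
}

#' @export
print.corrtest_result <- function(x, ...) {
  cat(sprintf(
    "corrtest_result: CorrScore = %.4f, P = %.4g (%d null replicates)\n",
    x$score, x$p_value, x$null_reps
  ))
  cat("  features:",
    paste(sprintf("%s=%.3f", names(x$features), x$features),
      collapse = ", "), "\n")
  invisible(x)
}
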