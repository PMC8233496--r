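#!/usr/bin/env Rscript
# Trains the CorrTest logistic classifier on the package's own simulator
# and prints the frozen coefficient block for R/corrtest-coef.R.
#
# Design: 400 trees per class. Null class = Yule topologies with
# independent lognormal branch rates (sdlog drawn U(0.15, 0.45));
# alternative class = geometric-Brownian autocorrelated rates (step log-sd
# drawn U(0.05, 0.30)). Tip counts cycle through {50, 100, 150, 200, 300}.
# Features: Pearson/Spearman parent-child and sister-sister correlations of
# RelTime lineage rates. Seed fixed below; rerun this script end-to-end to
# regenerate the coefficients.

suppressMessages(library(chronotree))

SEED <- 20260923L
N_PER_CLASS <- 400L
TIP_GRID <- c(50L, 100L, 150L, 200L, 300L)

set.seed(SEED)
make_class <- function(kind, n, offset) {
  feats <- matrix(NA_real_, n, 4)
  pars <- if (kind == "null") {
    stats::runif(n, 0.15, 0.45)
  } else {
    stats::runif(n, 0.05, 0.30)
  }
  for (b in seq_len(n)) {
    ntip <- TIP_GRID[((b - 1) %% length(TIP_GRID)) + 1]
    tt <- simulate_timetree(ntip, birth = 1, seed = offset + 2L * b)
    ph <- if (kind == "null") {
      apply_rate_model(tt, "lognormal", mu = 1, sdlog = pars[b],
        seed = offset + 2L * b + 1L)
    } else {
      apply_rate_model(tt, "autocorrelated", mu = 1, step_sdlog = pars[b],
        seed = offset + 2L * b + 1L)
    }
    feats[b, ] <- rate_features(ph)
  }
  feats
}

f0 <- make_class("null", N_PER_CLASS, SEED)
f1 <- make_class("alt", N_PER_CLASS, SEED + 10L * N_PER_CLASS)
x <- rbind(f0, f1)
colnames(x) <- c("pc_pearson", "pc_spearman", "sib_pearson", "sib_spearman")
y <- rep(0:1, each = N_PER_CLASS)

fit <- stats::glm(y ~ x, family = stats::binomial())
coef <- stats::coef(fit)
score <- stats::plogis(cbind(1, x) %*% coef)
cat(sprintf(
  "# training accuracy %.3f (null mean score %.3f, alt mean score %.3f)\n",
  mean((score > 0.5) == y), mean(score[y == 0]), mean(score[y == 1])
))
cat(".CORRTEST_COEF <- c(\n")
cat(sprintf("  intercept = %.6f, pc_pearson = %.6f, pc_spearman = %.6f,\n",
  coef[1], coef[2], coef[3]))
cat(sprintf("  sib_pearson = %.6f, sib_spearman = %.6f\n)\n",
  coef[4], coef[5]))
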