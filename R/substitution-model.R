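#' Substitution model specification
#'
#' A minimal model zoo covering the algorithmic paths the likelihood engine
#' needs: equal-rates JC for nucleotides, HKY with a transition/transversion
#' parameter and arbitrary base frequencies, and the Poisson equal-rates
#' model for amino acids. Optionally a discrete-gamma rate mixture.
#'
#' Rate matrices are normalized so one unit of branch length equals one
#' expected substitution per site at stationarity.
#'
#' @param type `"JC"`, `"HKY"` or `"Poisson"`.
#' @param freqs stationary frequencies (HKY only; JC/Poisson are uniform).
#'   Named or in alphabet order A,C,G,T.
#' @param kappa transition/transversion rate ratio (HKY only).
#' @param gamma_alpha shape of the discrete-gamma rate mixture, or `NULL`
#'   for a single rate class.
#' @param gamma_ncat number of discrete-gamma categories (default 4).
#' @return a `subst_model` object.
#' @export
#' @examples
#' substitution_model("HKY", freqs = c(0.3, 0.2, 0.2, 0.3), kappa = 4)
substitution_model <- function(type = c("JC", "HKY", "Poisson"),
                               freqs = NULL, kappa = 2,
                               gamma_alpha = NULL, gamma_ncat = 4L) {
  type <- match.arg(type)
  if (type == "Poisson") {
    states <- c(
      "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
    )
    alphabet <- "aa"
  } else {
    states <- c("A", "C", "G", "T")
    alphabet <- "nt"
  }
  s <- length(states)
  if (is.null(freqs)) freqs <- rep(1 / s, s)
  if (length(freqs) != s) stop("freqs must have length ", s)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be non-negative and sum to 1")
  }
  freqs <- freqs / sum(freqs)
  if (type %in% c("JC", "Poisson") && max(abs(freqs - 1 / s)) > 1e-12) {
    stop(type, " assumes uniform frequencies")
  }
  Q <- matrix(0, s, s, dimnames = list(states, states))
  if (type == "HKY") {
    if (kappa <= 0) stop("kappa must be > 0")
    transitions <- rbind(c("A", "G"), c("C", "T"))
    for (i in 1:s) {
      for (j in 1:s) {
        if (i == j) next
        ti <- any(
          (states[i] == transitions[, 1] & states[j] == transitions[, 2]) |
            (states[i] == transitions[, 2] & states[j] == transitions[, 1])
        )
        Q[i, j] <- freqs[j] * (if (ti) kappa else 1)
      }
    }
  } else {
    Q[] <- rep(freqs, each = s)
    diag(Q) <- 0
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  eig <- eigen(Q)
  rates <- 1
  if (!is.null(gamma_alpha)) {
    if (gamma_alpha <= 0) stop("gamma_alpha must be > 0")
    rates <- .discrete_gamma_rates(gamma_alpha, as.integer(gamma_ncat))
  }
  structure(
    list(
      type = type, alphabet = alphabet, states = states, freqs = freqs,
      kappa = if (type == "HKY") kappa else NA_real_,
      gamma_alpha = gamma_alpha, rates = rates,
      Q = Q, evec = eig$vectors, eval = Re(eig$values),
      ievec = solve(eig$vectors)
    ),
    class = "subst_model"
  )
}

# Mean rates of the k equiprobable discrete-gamma categories
# (mean-per-quantile-bin construction; category means average to 1).
.discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

#' Transition probability matrix P(d) for a model
#'
#' @param model a `subst_model`.
#' @param d branch length in expected substitutions per site (>= 0).
#' @return row-stochastic states-by-states matrix; `P(0)` is the identity.
#' @export
transition_matrix <- function(model, d) {
  if (d < 0) stop("branch length must be >= 0")
  P <- Re(model$evec %*% (exp(model$eval * d) * model$ievec))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(
    "subst_model:", x$type,
    sprintf("(%d states, %s)", length(x$states),
      if (x$alphabet == "nt") "nucleotide" else "amino acid"
    ), "\n"
  )
  if (x$type == "HKY") cat("  kappa:", x$kappa, "\n")
  if (!is.null(x$gamma_alpha)) {
    cat(
      "  discrete gamma: alpha =", x$gamma_alpha, ",",
      length(x$rates), "categories\n"
    )
  }
  invisible(x)
}
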