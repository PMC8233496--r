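#' Parse tip sampling dates from taxon names
#'
#' Extracts the `date` (or `year`) field of a tag-extraction spec from every
#' taxon name and converts it to a decimal year. Calendar dates use the
#' convention year + (day-of-year - 0.5)/days-in-year; year-only dates pin
#' to January 1 and month-only dates to the 1st (set `pin = "mid"` for
#' mid-interval); decimal years pass through.
#'
#' @param names character vector of taxon names.
#' @param spec tag-extraction spec containing a `date` field, e.g.
#'   `"name|date"`.
#' @param delim field delimiter.
#' @param pin `"start"` (default) or `"mid"` for partial dates.
#' @return a `tip_date_table` data frame with columns `taxon`, `date`
#'   (decimal year, `NA` when unknown), `provenance`, `known`; unparseable
#'   dates are flagged unknown with a warning attribute.
#' @export
#' @examples
#' parse_tip_dates(c("A|2020-07-02", "B|2021", "C|1999.25"), "name|date")
parse_tip_dates <- function(names, spec, delim = "|",
                            pin = c("start", "mid")) {
  pin <- match.arg(pin)
  fields <- strsplit(spec, delim, fixed = TRUE)[[1]]
  pos <- match("date", fields)
  if (is.na(pos)) pos <- match("year", fields)
  if (is.na(pos)) stop("spec must contain a 'date' (or 'year') field")
  warnings <- character(0)
  date <- rep(NA_real_, length(names))
  for (i in seq_along(names)) {
    parts <- strsplit(names[i], delim, fixed = TRUE)[[1]]
    if (length(parts) < pos) {
      warnings <- c(warnings, sprintf(
        "taxon '%s': no field at position %d", names[i], pos
      ))
      next
    }
    d <- .parse_date_token(parts[pos], pin = pin)
    if (is.null(d)) {
      warnings <- c(warnings, sprintf(
        "taxon '%s': unparseable date '%s'", names[i], parts[pos]
      ))
    } else {
      date[i] <- d$decimal
    }
  }
  if (length(warnings)) {
    warning("some tip dates could not be parsed (", length(warnings),
      " taxa flagged unknown)")
  }
  structure(
    data.frame(
      taxon = names, date = date, provenance = "parsed-from-name",
      known = !is.na(date), stringsAsFactors = FALSE
    ),
    class = c("tip_date_table", "data.frame"), warnings = warnings
  )
}

#' Read tip sampling dates from a TSV file
#'
#' Format: `taxon<TAB>date` per line, `#` comments and blank lines ignored;
#' dates in ISO (`YYYY[-MM[-DD]]`) or decimal-year form.
#'
#' @param file path.
#' @param pin partial-date convention, see [parse_tip_dates()].
#' @return a `tip_date_table`.
#' @export
read_tip_dates <- function(file, pin = c("start", "mid")) {
  pin <- match.arg(pin)
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  taxon <- character(0)
  date <- numeric(0)
  warnings <- character(0)
  for (ln in lines) {
    tok <- strsplit(ln, "\t")[[1]]
    if (length(tok) < 2) tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 2) {
      warnings <- c(warnings, paste("malformed line:", ln))
      next
    }
    d <- .parse_date_token(tok[2], pin = pin)
    taxon <- c(taxon, tok[1])
    if (is.null(d)) {
      warnings <- c(warnings, sprintf(
        "taxon '%s': unparseable date '%s'", tok[1], tok[2]
      ))
      date <- c(date, NA_real_)
    } else {
      date <- c(date, d$decimal)
    }
  }
  if (length(warnings)) warning(paste(warnings, collapse = "; "))
  structure(
    data.frame(
      taxon = taxon, date = date, provenance = "file",
      known = !is.na(date), stringsAsFactors = FALSE
    ),
    class = c("tip_date_table", "data.frame"), warnings = warnings
  )
}

# normalize dates input (tip_date_table, data frame or named vector) to a
# named numeric vector of decimal years
.dates_vector <- function(dates) {
  if (is.data.frame(dates)) {
    stats::setNames(dates$date, dates$taxon)
  } else if (is.numeric(dates) && !is.null(names(dates))) {
    dates
  } else {
    stop("dates must be a tip_date_table or a named numeric vector")
  }
}

#' Date a tree from tip sampling times (RelTime with dated tips)
#'
#' Estimates a global rate and a root time from serially sampled tips, then
#' dates every node. Lineage rates are first estimated with the relative-
#' rate recursion on a time-completed tree: each dated tip's terminal
#' branch is provisionally extended by `mu * (s_max - s_j)` so that, under a
#' clock, the completed tree is ultrametric (the provisional `mu` comes from
#' a root-to-tip regression and the completion is iterated). The
#' rate-adjusted root-to-tip depths D_j of the original tree are then
#' regressed on sampling dates, `D_j = mu * (s_j - T0)`, by least squares;
#' node times are `T0 + depth(node)/mu`. Confidence intervals come from
#' Monte-Carlo lognormal rate perturbations with a regression re-fit per
#' replicate.
#'
#' @param phy rooted `phylo` with branch lengths.
#' @param dates a `tip_date_table` (from [parse_tip_dates()] or
#'   [read_tip_dates()]) or a named numeric vector of decimal years; taxa
#'   with `NA` dates are excluded from the regression and dated post hoc.
#' @param n_iter rate-completion iterations (default 3; exact in one pass
#'   under a strict clock).
#' @param n_samples Monte-Carlo replicates for CIs.
#' @param rate_cv coefficient of variation of the rate perturbation.
#' @param seed optional integer seed.
#' @return a `tip_dating_fit`: list with `mu` (substitutions/site/year),
#'   `T0` (root date, decimal year), `time` (per-node dates; ancestors never
#'   later than descendants), `ci_lo`, `ci_hi`, `residuals` (observed minus
#'   fitted date per dated tip), `inferred` (logical per node: `TRUE` where
#'   the date is model-implied rather than observed), `rate` (lineage
#'   rates), `tree`.
#' @export
rtdt_fit <- function(phy, dates, n_iter = 3, n_samples = 2000,
                     rate_cv = 0.2, seed = NULL) {
  phy <- .binarize(phy)
  .validate_tree(phy)
  sv <- .dates_vector(dates)
  ix <- .tree_index(phy)
  dated <- intersect(names(sv)[!is.na(sv)], ix$tip_label)
  if (length(dated) < 3) {
    stop("need at least 3 dated tips (have ", length(dated), ")")
  }
  s <- sv[dated]
  if (max(s) - min(s) <= 0) {
    stop("tip dates are all identical; no temporal signal to fit")
  }
  tip_id <- match(dated, ix$tip_label)
  # raw root-to-tip depths
  raw_depth <- .node_depths(ix, ix$blen)
  fit0 <- stats::lm.fit(cbind(1, s), raw_depth[tip_id])
  mu <- fit0$coefficients[2]
  if (!is.finite(mu) || mu <= 0) {
    stop("no temporal signal: root-to-tip divergence does not increase ",
      "with sampling date (fitted rate <= 0)")
  }
  rt <- NULL
  adj <- NULL
  undated_id <- setdiff(seq_len(ix$n_tip), tip_id)
  for (iter in seq_len(n_iter)) {
    ext <- phy
    ext_ix_blen <- ix$blen
    ext_ix_blen[tip_id] <- ix$blen[tip_id] + mu * (max(s) - s)
    if (length(undated_id)) {
      # undated tips are provisionally pinned to the deepest sampled
      # horizon so they do not distort the completed (ultrametricized) tree
      h_star <- max(raw_depth[tip_id] + mu * (max(s) - s))
      ext_ix_blen[undated_id] <- ix$blen[undated_id] +
        pmax(0, h_star - raw_depth[undated_id])
    }
    ext$edge.length <- ext_ix_blen[ext$edge[, 2]]
    rt <- reltime(ext)
    adj <- ix$blen / rt$rate
    adj[ix$root] <- 0
    depth <- .node_depths(ix, adj)
    fit <- stats::lm.fit(cbind(1, s), depth[tip_id])
    mu_new <- fit$coefficients[2]
    if (!is.finite(mu_new) || mu_new <= 0) {
      stop("no temporal signal after rate adjustment (fitted rate <= 0)")
    }
    mu <- mu_new
  }
  depth <- .node_depths(ix, adj)
  T0 <- -fit$coefficients[1] / mu
  time <- T0 + depth / mu
  residuals <- stats::setNames(s - time[tip_id], dated)
  inferred <- rep(TRUE, ix$n_all)
  inferred[tip_id] <- FALSE
  # Monte-Carlo CIs: perturb lineage rates, rebuild depths, re-fit
  if (!is.null(seed)) set.seed(seed)
  if (n_samples < 100) stop("n_samples must be >= 100")
  sdlog <- sqrt(log(1 + rate_cv^2))
  nonroot <- setdiff(seq_len(ix$n_all), ix$root)
  sbar <- mean(s)
  cvec <- (s - sbar) / sum((s - sbar)^2)
  A <- matrix(0, ix$n_all, n_samples)
  A[nonroot, ] <- adj[nonroot] / exp(matrix(
    stats::rnorm(length(nonroot) * n_samples, -sdlog^2 / 2, sdlog),
    length(nonroot), n_samples
  ))
  D <- matrix(0, ix$n_all, n_samples) # root-to-node depths per replicate
  for (v in c(setdiff(ix$node_pre, ix$root), seq_len(ix$n_tip))) {
    D[v, ] <- D[ix$parent[v], ] + A[v, ]
  }
  mu_r <- as.vector(cvec %*% D[tip_id, , drop = FALSE])
  T0_r <- sbar - colMeans(D[tip_id, , drop = FALSE]) / mu_r
  Tmat <- t(sweep(D, 2, mu_r, "/")) + T0_r
  ok <- is.finite(mu_r) & mu_r > 0
  if (mean(ok) < 0.9) {
    warning(sum(!ok), " of ", n_samples,
      " Monte-Carlo replicates lost temporal signal and were dropped")
  }
  ci_lo <- apply(Tmat[ok, , drop = FALSE], 2, stats::quantile,
    probs = 0.025, names = FALSE)
  ci_hi <- apply(Tmat[ok, , drop = FALSE], 2, stats::quantile,
    probs = 0.975, names = FALSE)
  structure(
    list(
      tree = phy, ix = ix, mu = unname(mu), T0 = unname(T0), time = time,
      ci_lo = pmin(ci_lo, time), ci_hi = pmax(ci_hi, time),
      mu_ci = stats::quantile(mu_r[ok], c(0.025, 0.975), names = FALSE),
      residuals = residuals, inferred = inferred, rate = rt$rate,
      depth = depth, dated_tips = dated, dates = s,
      t_rel = NULL, time_reported = NULL
    ),
    class = "tip_dating_fit"
  )
}

# root-to-node path sums of per-node branch values
.node_depths <- function(ix, blen) {
  depth <- numeric(ix$n_all)
  for (v in setdiff(ix$node_pre, ix$root)) {
    depth[v] <- depth[ix$parent[v]] + blen[v]
  }
  for (v in seq_len(ix$n_tip)) {
    depth[v] <- depth[ix$parent[v]] + blen[v]
  }
  depth
}

#' Dates of tips not used in the regression
#'
#' Tips with unknown sampling dates are placed on the fitted time axis like
#' internal nodes (`T0 + depth/mu`) and flagged as inferred.
#'
#' @param fit a `tip_dating_fit`.
#' @return data frame with `taxon`, `date` (observed or inferred decimal
#'   year), `inferred` flag.
#' @export
tip_times <- function(fit) {
  stopifnot(inherits(fit, "tip_dating_fit"))
  ix <- fit$ix
  tips <- seq_len(ix$n_tip)
  observed <- ix$tip_label %in% fit$dated_tips
  date <- fit$time[tips]
  date[observed] <- fit$dates[ix$tip_label[observed]]
  data.frame(
    taxon = ix$tip_label, date = date, inferred = !observed,
    stringsAsFactors = FALSE
  )
}

#' @export
print.tip_dating_fit <- function(x, ...) {
  cat(sprintf(
    "tip_dating_fit: mu = %.6g subs/site/year [%.4g, %.4g], root %.4f\n",
    x$mu, x$mu_ci[1], x$mu_ci[2], x$T0
  ))
  cat(sprintf(
    "  %d dated tips spanning %.3f-%.3f\n",
    length(x$dated_tips), min(x$dates), max(x$dates)
  ))
  invisible(x)
}
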