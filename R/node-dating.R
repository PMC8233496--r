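#' Node calibration constraints
#'
#' A calibration attaches prior information about a node's true age to the
#' tree: a probability density (normal, lognormal, exponential, uniform), a
#' known point time, or a hard minimum/maximum bound. The node is selected
#' either as the MRCA of two named taxa or by internal-node label. Times are
#' in the user's units (e.g. Ma before present, consistent across
#' calibrations).
#'
#' Parameterizations: `normal(mean, sd)`; `lognormal(offset, mean, sd)` —
#' lognormal with log-scale mean/sd on (time - offset); `exponential(offset,
#' decay)` — rate-parameter `decay` on (time - offset); `uniform(min, max)`;
#' `point(time)`; `minbound(time)`; `maxbound(time)`.
#'
#' @param kind one of `"normal"`, `"lognormal"`, `"exponential"`,
#'   `"uniform"`, `"point"`, `"minbound"`, `"maxbound"`.
#' @param mrca character vector of two taxon names (or `NULL`).
#' @param node internal node label (or `NULL`); exactly one of `mrca`/`node`.
#' @param ... kind-specific parameters (see above).
#' @return a `calibration` object.
#' @export
#' @examples
#' calibration("normal", mrca = c("A", "B"), mean = 50, sd = 5)
calibration <- function(kind, mrca = NULL, node = NULL, ...) {
  kind <- match.arg(kind, c(
    "normal", "lognormal", "exponential", "uniform",
    "point", "minbound", "maxbound"
  ))
  if (is.null(mrca) == is.null(node)) {
    stop("specify exactly one of 'mrca' or 'node'")
  }
  if (!is.null(mrca) && length(mrca) != 2) {
    stop("'mrca' must name exactly two taxa")
  }
  p <- list(...)
  need <- switch(kind,
    normal = c("mean", "sd"),
    lognormal = c("offset", "mean", "sd"),
    exponential = c("offset", "decay"),
    uniform = c("min", "max"),
    point = "time", minbound = "time", maxbound = "time"
  )
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop(kind, " calibration needs parameter(s): ",
      paste(missing, collapse = ", "))
  }
  p <- p[need]
  if (kind %in% c("normal", "lognormal") && p$sd <= 0) stop("sd must be > 0")
  if (kind == "exponential" && p$decay <= 0) stop("decay must be > 0")
  if (kind == "uniform" && p$min >= p$max) stop("min must be < max")
  if (kind %in% c("lognormal", "exponential") && p$offset < 0) {
    stop("offset must be >= 0")
  }
  structure(
    c(list(kind = kind, mrca = mrca, node = node), p),
    class = "calibration"
  )
}

#' Read calibrations from a text file
#'
#' One record per line; `#` starts a comment; blank lines are ignored.
#' Node selectors are `mrca TaxonA TaxonB` or `node NodeName`; the selector
#' is followed by the calibration kind and `key=value` parameters:
#' ```
#' mrca TaxonA TaxonB normal mean=50 sd=5
#' node NodeName uniform min=40 max=60
#' mrca A B exponential offset=30 decay=0.1
#' mrca A B point time=100
#' mrca A B minbound time=40
#' rate value=0.01
#' ```
#' A `rate value=...` line requests fixed-rate calibration instead
#' (mutually exclusive with node calibrations in one run).
#'
#' @param file path to the calibration file.
#' @return list with `calibrations` (list of [calibration()] objects) and
#'   `rate` (numeric or `NULL`).
#' @export
read_calibrations <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cals <- list()
  rate <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    kv <- function(toks) {
      pairs <- strsplit(toks, "=", fixed = TRUE)
      bad <- lengths(pairs) != 2
      if (any(bad)) {
        stop("malformed key=value token '", toks[bad][1], "' in line: ", ln)
      }
      stats::setNames(
        lapply(pairs, function(p) as.numeric(p[2])),
        vapply(pairs, `[`, character(1), 1)
      )
    }
    if (tok[1] == "rate") {
      p <- kv(tok[-1])
      if (is.null(p$value)) stop("rate line needs value=: ", ln)
      rate <- p$value
    } else if (tok[1] == "mrca") {
      if (length(tok) < 4) stop("malformed mrca line: ", ln)
      cals[[length(cals) + 1]] <- do.call(calibration, c(
        list(kind = tok[4], mrca = tok[2:3]), kv(tok[-(1:4)])
      ))
    } else if (tok[1] == "node") {
      if (length(tok) < 3) stop("malformed node line: ", ln)
      cals[[length(cals) + 1]] <- do.call(calibration, c(
        list(kind = tok[3], node = tok[2]), kv(tok[-(1:3)])
      ))
    } else {
      stop("unrecognized calibration line: ", ln)
    }
  }
  list(calibrations = cals, rate = rate)
}

# log density of a calibration at age t (vectorized over t)
.cal_logdens <- function(cal, t) {
  switch(cal$kind,
    normal = stats::dnorm(t, cal$mean, cal$sd, log = TRUE),
    lognormal = stats::dlnorm(t - cal$offset, cal$mean, cal$sd, log = TRUE),
    exponential = stats::dexp(t - cal$offset, cal$decay, log = TRUE),
    uniform = stats::dunif(t, cal$min, cal$max, log = TRUE),
    stop("no density for kind ", cal$kind)
  )
}

# random age draw from a density calibration
.cal_draw <- function(cal, n) {
  switch(cal$kind,
    normal = stats::rnorm(n, cal$mean, cal$sd),
    lognormal = cal$offset + stats::rlnorm(n, cal$mean, cal$sd),
    exponential = cal$offset + stats::rexp(n, cal$decay),
    uniform = stats::runif(n, cal$min, cal$max),
    point = rep(cal$time, n)
  )
}

# resolve the calibrated node id on rt$tree
.cal_node <- function(cal, rt) {
  phy <- rt$tree
  if (!is.null(cal$mrca)) {
    miss <- setdiff(cal$mrca, phy$tip.label)
    if (length(miss)) {
      stop("calibration taxa not in tree: ", paste(miss, collapse = ", "))
    }
    ape::getMRCA(phy, cal$mrca)
  } else {
    if (is.null(phy$node.label) || !(cal$node %in% phy$node.label)) {
      stop("no internal node labelled '", cal$node, "'")
    }
    length(phy$tip.label) + match(cal$node, phy$node.label)
  }
}

.cal_label <- function(cal) {
  sel <- if (!is.null(cal$mrca)) {
    paste0("mrca(", cal$mrca[1], ",", cal$mrca[2], ")")
  } else {
    paste0("node(", cal$node, ")")
  }
  paste0(sel, " ", cal$kind)
}

#' Convert relative times to absolute times with node calibrations
#'
#' Fits one global scaling factor f so that absolute node ages are
#' `f * t_rel`. Density calibrations (normal/lognormal/exponential, and
#' uniform within its support) contribute to f through the sum of their
#' log densities evaluated at the implied ages, which is maximized over the
#' feasible interval; point calibrations and hard min/max bounds constrain
#' that interval. Ages are then clamped into any per-node bounds with an
#' upward monotonicity-repair pass (a parent is at least as old as its
#' children). Confidence intervals come from the Monte-Carlo relative-time
#' sample matrix with a fresh draw from every density calibration per
#' replicate.
#'
#' @param rt a `reltime_result`.
#' @param calibrations list of [calibration()] objects (>= 1).
#' @param n_samples Monte-Carlo replicates for CIs (default 10000).
#' @param rate_cv rate-heterogeneity coefficient of variation for the
#'   Monte-Carlo perturbation.
#' @param seed optional integer seed.
#' @return a `timetree_result`: list with `tree`, `time` (per-node absolute
#'   age), `ci_lo`, `ci_hi` (2.5/97.5 percentiles), scaling factor `f`,
#'   `t_rel`, `rate`, `time_reported` and per-calibration `diagnostics`
#'   (density value at the fitted age).
#' @export
fit_time_scale <- function(rt, calibrations, n_samples = 10000,
                           rate_cv = 0.2, seed = NULL) {
  stopifnot(inherits(rt, "reltime_result"))
  if (inherits(calibrations, "calibration")) {
    calibrations <- list(calibrations)
  }
  if (!length(calibrations)) stop("at least one calibration is required")
  nodes <- vapply(calibrations, .cal_node, integer(1), rt = rt)
  tau <- rt$t_rel[nodes]
  if (any(tau <= 0)) {
    stop("calibration on a node with zero relative time: ",
      .cal_label(calibrations[[which(tau <= 0)[1]]]))
  }
  dens_kind <- c("normal", "lognormal", "exponential")
  # feasible interval of f from hard constraints and density supports
  lo <- 0
  hi <- Inf
  lo_by <- hi_by <- NA_character_
  for (i in seq_along(calibrations)) {
    cal <- calibrations[[i]]
    lab <- .cal_label(cal)
    new_lo <- lo
    new_hi <- hi
    if (cal$kind == "point") {
      new_lo <- max(lo, cal$time / tau[i])
      new_hi <- min(hi, cal$time / tau[i])
    } else if (cal$kind == "minbound") {
      new_lo <- max(lo, cal$time / tau[i])
    } else if (cal$kind == "maxbound") {
      new_hi <- min(hi, cal$time / tau[i])
    } else if (cal$kind == "uniform") {
      new_lo <- max(lo, cal$min / tau[i])
      new_hi <- min(hi, cal$max / tau[i])
    } else if (cal$kind %in% c("lognormal", "exponential")) {
      new_lo <- max(lo, cal$offset / tau[i])
    }
    if (new_lo > lo) lo_by <- lab
    if (new_hi < hi) hi_by <- lab
    lo <- new_lo
    hi <- new_hi
    if (lo > hi * (1 + 1e-12)) {
      stop(
        "infeasible calibration set: '", lo_by, "' requires f >= ",
        signif(lo, 8), " but '", hi_by, "' requires f <= ", signif(hi, 8)
      )
    }
  }
  is_dens <- vapply(calibrations, function(c) c$kind %in% dens_kind,
    logical(1))
  is_unif <- vapply(calibrations, function(c) c$kind == "uniform",
    logical(1))
  obj <- function(f) {
    sum(vapply(which(is_dens), function(i) {
      .cal_logdens(calibrations[[i]], f * tau[i])
    }, numeric(1)))
  }
  if (hi - lo < 1e-12) {
    f <- lo
  } else if (any(is_dens)) {
    all_normal <- all(vapply(calibrations[is_dens], function(c) {
      c$kind == "normal"
    }, logical(1)))
    if (all_normal) {
      # weighted least squares closed form
      mu <- vapply(calibrations[is_dens], `[[`, numeric(1), "mean")
      sd <- vapply(calibrations[is_dens], `[[`, numeric(1), "sd")
      tv <- tau[is_dens]
      f <- sum(mu * tv / sd^2) / sum(tv^2 / sd^2)
      f <- min(max(f, lo), hi)
    } else {
      cap <- hi
      if (!is.finite(cap)) {
        qmax <- vapply(which(is_dens), function(i) {
          cal <- calibrations[[i]]
          q <- switch(cal$kind,
            normal = cal$mean + 12 * cal$sd,
            lognormal = cal$offset + stats::qlnorm(1 - 1e-9, cal$mean, cal$sd),
            exponential = cal$offset + stats::qexp(1 - 1e-9, cal$decay)
          )
          q / tau[i]
        }, numeric(1))
        cap <- max(qmax, lo * 2 + 1)
      }
      opt <- stats::optimize(obj, c(lo, cap), maximum = TRUE, tol = 1e-9)
      f <- opt$maximum
    }
    if (!is.finite(obj(f))) {
      stop("density calibrations have zero density everywhere on the ",
        "feasible interval [", signif(lo, 6), ", ", signif(hi, 6), "]")
    }
  } else if (any(is_unif)) {
    if (!is.finite(hi)) {
      stop("only unbounded constraints given; cannot determine a scale")
    }
    f <- (lo + hi) / 2
  } else {
    stop("need at least one density, uniform or point calibration ",
      "to set the time scale")
  }
  time <- f * rt$t_rel
  # per-node hard windows from bounds/uniform/point
  win_lo <- rep(-Inf, rt$ix$n_all)
  win_hi <- rep(Inf, rt$ix$n_all)
  for (i in seq_along(calibrations)) {
    cal <- calibrations[[i]]
    v <- nodes[i]
    if (cal$kind == "point") {
      win_lo[v] <- max(win_lo[v], cal$time)
      win_hi[v] <- min(win_hi[v], cal$time)
    } else if (cal$kind == "minbound") {
      win_lo[v] <- max(win_lo[v], cal$time)
    } else if (cal$kind == "maxbound") {
      win_hi[v] <- min(win_hi[v], cal$time)
    } else if (cal$kind == "uniform") {
      win_lo[v] <- max(win_lo[v], cal$min)
      win_hi[v] <- min(win_hi[v], cal$max)
    }
  }
  time <- .clamp_monotone(time, win_lo, win_hi, rt$ix)
  mc <- monte_carlo_time_samples(rt,
    n_samples = max(n_samples, 100),
    rate_cv = rate_cv, seed = seed
  )
  ci <- .calibration_ci(mc, calibrations, nodes, win_lo, win_hi, rt$ix)
  diagnostics <- data.frame(
    calibration = vapply(calibrations, .cal_label, character(1)),
    node = nodes,
    fitted_time = time[nodes],
    density = vapply(seq_along(calibrations), function(i) {
      cal <- calibrations[[i]]
      if (cal$kind %in% c(dens_kind, "uniform")) {
        exp(.cal_logdens(cal, time[nodes[i]]))
      } else {
        NA_real_
      }
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  .timetree_result(rt, time, ci$lo, ci$hi, f, diagnostics)
}

# CI machinery shared by density and fixed-rate dating: per replicate, draw
# an age from every density/point calibration, least-squares fit f_r against
# the replicate's relative times, clamp into the replicate's feasible
# interval, and scale.
.calibration_ci <- function(mc, calibrations, nodes, win_lo, win_hi, ix) {
  ns <- mc$n_samples
  drawable <- vapply(calibrations, function(c) {
    c$kind %in% c("normal", "lognormal", "exponential", "uniform", "point")
  }, logical(1))
  draws <- matrix(0, ns, sum(drawable))
  j <- 0
  for (i in which(drawable)) {
    j <- j + 1
    draws[, j] <- .cal_draw(calibrations[[i]], ns)
  }
  tau_r <- mc$t_rel[, nodes[drawable], drop = FALSE]
  f_r <- rowSums(draws * tau_r) / rowSums(tau_r^2)
  # replicate feasible interval from hard bounds
  lo_r <- rep(0, ns)
  hi_r <- rep(Inf, ns)
  for (i in seq_along(calibrations)) {
    cal <- calibrations[[i]]
    tr <- mc$t_rel[, nodes[i]]
    if (cal$kind == "minbound") lo_r <- pmax(lo_r, cal$time / tr)
    if (cal$kind == "maxbound") hi_r <- pmin(hi_r, cal$time / tr)
    if (cal$kind == "point") {
      lo_r <- pmax(lo_r, cal$time / tr)
      hi_r <- pmin(hi_r, cal$time / tr)
    }
  }
  f_r <- pmin(pmax(f_r, lo_r), pmax(hi_r, lo_r))
  times_r <- mc$t_rel * f_r
  lo <- apply(times_r, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(times_r, 2, stats::quantile, probs = 0.975, names = FALSE)
  lo <- pmin(pmax(lo, win_lo), win_hi)
  hi <- pmin(pmax(hi, win_lo), win_hi)
  list(lo = lo, hi = hi)
}

# clamp node ages into per-node windows, then repair parent >= child order
# by an upward max-propagation pass
.clamp_monotone <- function(time, win_lo, win_hi, ix) {
  time <- pmin(pmax(time, win_lo), win_hi)
  for (v in ix$node_po) {
    time[v] <- max(time[v], time[ix$children[[v]]])
  }
  time
}

.timetree_result <- function(rt, time, ci_lo, ci_hi, f, diagnostics) {
  ci_lo <- pmin(ci_lo, time)
  ci_hi <- pmax(ci_hi, time)
  structure(
    list(
      tree = rt$tree, ix = rt$ix, time = time, ci_lo = ci_lo, ci_hi = ci_hi,
      f = f, t_rel = rt$t_rel, rate = rt$rate,
      time_reported = rt$time_reported, diagnostics = diagnostics
    ),
    class = "timetree_result"
  )
}

#' Fixed-rate calibration of the molecular clock
#'
#' Converts adjusted node heights directly into ages through a known
#' evolutionary rate: `time(node) = height(node) / rate`. Confidence
#' intervals reflect rate heterogeneity only.
#'
#' @param rt a `reltime_result`.
#' @param rate substitutions/site per time unit (> 0).
#' @param n_samples,rate_cv,seed Monte-Carlo CI controls as in
#'   [fit_time_scale()].
#' @return a `timetree_result`.
#' @export
#' @examples
#' rt <- reltime(read_newick("((A:1,B:1):1,C:2);"))
#' fixed_rate_scale(rt, rate = 0.01, n_samples = 200, seed = 1)$time
fixed_rate_scale <- function(rt, rate, n_samples = 10000, rate_cv = 0.2,
                             seed = NULL) {
  stopifnot(inherits(rt, "reltime_result"))
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  time <- rt$height / rate
  mc <- monte_carlo_time_samples(rt,
    n_samples = max(n_samples, 100),
    rate_cv = rate_cv, seed = seed
  )
  times_r <- mc$height / rate
  lo <- apply(times_r, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(times_r, 2, stats::quantile, probs = 0.975, names = FALSE)
  f <- rt$height[rt$ix$root] / rate
  .timetree_result(rt, time, lo, hi, f, diagnostics = NULL)
}

#' @export
print.timetree_result <- function(x, ...) {
  cat(sprintf(
    "timetree_result: %d tips; root age %.6g [%.6g, %.6g]; f = %.6g\n",
    x$ix$n_tip, x$time[x$ix$root], x$ci_lo[x$ix$root], x$ci_hi[x$ix$root],
    x$f
  ))
  invisible(x)
}

# Two spanning taxa identifying a node (first tip of each of the first two
# child subtrees; a tip is identified by itself twice).
.span_taxa <- function(ix, v) {
  if (v <= ix$n_tip) return(c(ix$tip_label[v], ix$tip_label[v]))
  first_tip <- function(u) {
    while (u > ix$n_tip) u <- ix$children[[u]][1]
    ix$tip_label[u]
  }
  ch <- ix$children[[v]]
  c(first_tip(ch[1]), first_tip(ch[length(ch)]))
}

#' Tabular export of a dated tree
#'
#' One row per node: node id, two spanning taxa (a stable fingerprint of the
#' clade), relative time, absolute time, CI bounds and lineage rate.
#' Outgroup-masked nodes get `NA` times.
#'
#' @param tt a `timetree_result` (or `tip_dating_fit`).
#' @param file optional output path (TSV).
#' @return the data frame, invisibly when `file` is given.
#' @export
timetree_table <- function(tt, file = NULL) {
  ix <- tt$ix
  span <- t(vapply(seq_len(ix$n_all), .span_taxa, character(2), ix = ix))
  rep_mask <- if (!is.null(tt$time_reported)) tt$time_reported else TRUE
  df <- data.frame(
    node = seq_len(ix$n_all),
    taxon_a = span[, 1], taxon_b = span[, 2],
    rel_time = if (!is.null(tt$t_rel)) tt$t_rel else NA_real_,
    time = ifelse(rep_mask, tt$time, NA_real_),
    ci_lo = ifelse(rep_mask, tt$ci_lo, NA_real_),
    ci_hi = ifelse(rep_mask, tt$ci_hi, NA_real_),
    rate = tt$rate,
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Annotated newick export of a dated tree
#'
#' Embeds per-node `[&time=...,ci_lo=...,ci_hi=...]` comment blocks.
#'
#' @param tt a `timetree_result` (or `tip_dating_fit`).
#' @param file optional output path.
#' @return the newick string.
#' @export
timetree_newick <- function(tt, file = NULL) {
  ann <- data.frame(
    node = seq_len(tt$ix$n_all),
    time = tt$time, ci_lo = tt$ci_lo, ci_hi = tt$ci_hi
  )
  write_newick(tt$tree, annotations = ann, file = file)
}
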