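clock3 <- function() reltime(read_newick("((A:1,B:1):1,C:2);"))

test_that("a single point calibration scales all times proportionally", {
  rt <- clock3()
  tt <- fit_time_scale(rt,
    calibration("point", mrca = c("A", "B"), time = 50),
    n_samples = 200, seed = 1
  )
  expect_equal(tt$f, 100, tolerance = 1e-9)
  expect_equal(tt$time[rt$ix$root], 100, tolerance = 1e-9)
  expect_equal(tt$time, 100 * rt$t_rel, tolerance = 1e-9)
})

test_that("two normal calibrations maximize the summed log density (f = 95)", {
  rt <- clock3()
  ab <- ape::getMRCA(rt$tree, c("A", "B"))
  tt <- fit_time_scale(rt, list(
    calibration("normal", mrca = c("A", "B"), mean = 50, sd = 5),
    calibration("normal", mrca = c("A", "C"), mean = 90, sd = 10)
  ), n_samples = 200, seed = 1)
  expect_equal(tt$f, 95, tolerance = 1e-6)
  expect_equal(tt$time[ab], 47.5, tolerance = 1e-6)
  expect_equal(tt$time[rt$ix$root], 95, tolerance = 1e-6)
  expect_equal(tt$diagnostics$density[1],
    stats::dnorm(47.5, 50, 5), tolerance = 1e-9)
})

test_that("uniform bound plus root point: scaling from the point, CI truncated", {
  rt <- clock3()
  ab <- ape::getMRCA(rt$tree, c("A", "B"))
  tt <- fit_time_scale(rt, list(
    calibration("uniform", mrca = c("A", "B"), min = 40, max = 60),
    calibration("point", mrca = c("A", "C"), time = 100)
  ), n_samples = 2000, seed = 7)
  expect_equal(tt$f, 100, tolerance = 1e-9)
  expect_equal(tt$time[ab], 50, tolerance = 1e-9)
  expect_gte(tt$ci_lo[ab], 40)
  expect_lte(tt$ci_hi[ab], 60)
})

test_that("mixed density kinds fit and respect offsets", {
  rt <- clock3()
  tt <- fit_time_scale(rt, list(
    calibration("exponential", mrca = c("A", "B"), offset = 30,
      decay = 0.1),
    calibration("lognormal", mrca = c("A", "C"),
      offset = 50, mean = log(30), sd = 0.5)
  ), n_samples = 200, seed = 2)
  ab <- ape::getMRCA(rt$tree, c("A", "B"))
  expect_gte(tt$time[ab], 30) # exponential support
  expect_gte(tt$time[rt$ix$root], 50) # lognormal support
  expect_true(all(diff(tt$time[c(ab, rt$ix$root)]) >= 0))
})

test_that("infeasible constraint sets raise a conflict error", {
  rt <- clock3()
  expect_error(
    fit_time_scale(rt, list(
      calibration("minbound", mrca = c("A", "B"), time = 80),
      calibration("maxbound", mrca = c("A", "C"), time = 100)
    ), n_samples = 200),
    "infeasible"
  )
  expect_error(fit_time_scale(rt, list()), "at least one")
  expect_error(
    fit_time_scale(rt, list(
      calibration("minbound", mrca = c("A", "B"), time = 10)
    )),
    "density"
  )
})

test_that("adding calibrations can only narrow the feasible interval", {
  rt <- clock3()
  base <- list(calibration("uniform", mrca = c("A", "C"), min = 80,
    max = 120))
  t1 <- fit_time_scale(rt, base, n_samples = 200, seed = 3)
  narrower <- c(base, list(
    calibration("minbound", mrca = c("A", "B"), time = 48),
    calibration("maxbound", mrca = c("A", "C"), time = 110)
  ))
  t2 <- fit_time_scale(rt, narrower, n_samples = 200, seed = 3)
  # f of the narrowed problem lies inside the base feasible interval
  expect_gte(t2$f, 80)
  expect_lte(t2$f, 120)
  expect_gte(t2$f, 96) # minbound 48 at t_rel 0.5
  expect_lte(t2$f, 110)
})

test_that("parent >= child order survives clamping (monotonicity repair)", {
  # the repair pass itself, on an inverted input
  ix <- clock3()$ix
  time <- c(0, 0, 0, 80, 90) # child (node 5) above its parent (root 4)
  repaired <- chronotree:::.clamp_monotone(time, rep(-Inf, 5), rep(Inf, 5),
    ix)
  expect_equal(repaired[4], 90)
  expect_equal(repaired[5], 90)
  # and end-to-end: bounds plus noisy replicates never break the order
  rt <- clock3()
  tt <- fit_time_scale(rt, list(
    calibration("point", mrca = c("A", "C"), time = 100),
    calibration("uniform", mrca = c("A", "B"), min = 40, max = 60)
  ), n_samples = 2000, rate_cv = 0.5, seed = 4)
  for (v in tt$ix$node_po) {
    expect_true(all(tt$time[v] >= tt$time[tt$ix$children[[v]]] - 1e-9))
  }
  expect_true(all(tt$ci_lo <= tt$time + 1e-9))
  expect_true(all(tt$ci_hi >= tt$time - 1e-9))
})

test_that("fixed-rate calibration divides heights by the rate", {
  rt <- clock3()
  ab <- ape::getMRCA(rt$tree, c("A", "B"))
  tt <- fixed_rate_scale(rt, 0.01, n_samples = 200, seed = 5)
  expect_equal(tt$time[rt$ix$root], 200, tolerance = 1e-9)
  expect_equal(tt$time[ab], 100, tolerance = 1e-9)
  t1 <- fixed_rate_scale(rt, 1, n_samples = 200, seed = 5)
  expect_equal(t1$time, rt$height, tolerance = 1e-12)
  t2 <- fixed_rate_scale(rt, 0.02, n_samples = 200, seed = 5)
  expect_equal(t2$time, tt$time / 2, tolerance = 1e-9)
  expect_error(fixed_rate_scale(rt, 0), "> 0")
})

test_that("calibration files parse the documented grammar", {
  f <- tempfile()
  writeLines(c(
    "# calibrations for the toy tree",
    "mrca A B normal mean=50 sd=5",
    "",
    "node N1 uniform min=40 max=60",
    "mrca A B exponential offset=30 decay=0.1",
    "mrca A B point time=100",
    "mrca A B minbound time=40"
  ), f)
  got <- read_calibrations(f)
  expect_length(got$calibrations, 5)
  expect_null(got$rate)
  kinds <- vapply(got$calibrations, `[[`, character(1), "kind")
  expect_equal(kinds,
    c("normal", "uniform", "exponential", "point", "minbound"))
  expect_equal(got$calibrations[[1]]$sd, 5)
  expect_equal(got$calibrations[[2]]$node, "N1")

  writeLines("rate value=0.01", f)
  expect_equal(read_calibrations(f)$rate, 0.01)
  writeLines("mrca A B normal mean=50", f)
  expect_error(read_calibrations(f), "sd")
  writeLines("frobnicate A B", f)
  expect_error(read_calibrations(f), "unrecognized")
})

test_that("calibration parameter validation catches bad values", {
  expect_error(calibration("normal", mrca = c("A", "B"), mean = 1, sd = 0),
    "sd")
  expect_error(calibration("uniform", mrca = c("A", "B"), min = 5, max = 5),
    "min")
  expect_error(calibration("exponential", mrca = c("A", "B"), offset = -1,
    decay = 1), "offset")
  expect_error(calibration("point", time = 5), "mrca")
})

test_that("density CIs cover truth on calibrated simulations", {
  covered <- 0
  total <- 0
  cv <- sqrt(exp(0.09) - 1)
  for (b in 1:15) {
    tt <- simulate_timetree(30, 1, seed = 700 + 2 * b)
    ph <- apply_rate_model(tt, "lognormal", mu = 0.05, sdlog = 0.3,
      seed = 700 + 2 * b + 1)
    rt <- reltime(ph)
    A <- tt$age[rt$ix$root]
    cal <- calibration("normal", mrca = root_spanning_tips(rt),
      mean = A, sd = 0.1 * A)
    fit <- fit_time_scale(rt, list(cal), n_samples = 1000, rate_cv = cv,
      seed = 800 + b)
    internal <- setdiff((rt$ix$n_tip + 1):rt$ix$n_all, rt$ix$root)
    covered <- covered + sum(
      fit$ci_lo[internal] - 1e-9 <= tt$age[internal] &
        tt$age[internal] <= fit$ci_hi[internal] + 1e-9
    )
    total <- total + length(internal)
  }
  expect_gte(covered / total, 0.85)
})

test_that("timetree exports carry times, CIs and spanning taxa", {
  rt <- clock3()
  tt <- fit_time_scale(rt,
    calibration("point", mrca = c("A", "B"), time = 50),
    n_samples = 200, seed = 1
  )
  df <- timetree_table(tt)
  expect_equal(nrow(df), rt$ix$n_all)
  expect_true(all(c("node", "taxon_a", "taxon_b", "rel_time", "time",
    "ci_lo", "ci_hi", "rate") %in% names(df)))
  expect_equal(df$time[df$node == rt$ix$root], 100, tolerance = 1e-9)
  nwk <- timetree_newick(tt)
  expect_match(nwk, "\\[&time=")
  expect_true(ape::all.equal.phylo(read_newick(nwk), rt$tree))
})
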