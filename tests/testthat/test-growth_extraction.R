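test_that("background subtraction averages the medium-only wells", {
  curves <- subtract_background(toy_run(), toy_layout())
  expect_length(curves, 2L)
  a1 <- curves[[1L]]
  expect_equal(a1$od, c(0.10, 0.20, 0.40))

  # two background wells -> their mean at each timepoint
  od <- cbind(B1 = c(0.07, 0.07), B2 = c(0.09, 0.09), A1 = c(0.18, 0.28))
  run <- plate_run("p", c(0, 1), od)
  lay <- plate_layout(data.frame(
    well_id = c("B1", "B2", "A1"),
    role = c("background", "background", "sample"),
    combination_id = c(NA, NA, "c1")))
  expect_equal(subtract_background(run, lay)[[1L]]$od, c(0.10, 0.20))

  # a sample equal to the background is zero after correction
  od2 <- cbind(B1 = c(0.08, 0.08, 0.08, 0.08), A1 = c(0.08, 0.08, 0.08, 0.08))
  run2 <- plate_run("p2", 0:3, od2)
  lay2 <- plate_layout(data.frame(
    well_id = c("B1", "A1"), role = c("background", "sample"),
    combination_id = c(NA, "c1")))
  cv <- subtract_background(run2, lay2)[[1L]]
  expect_equal(cv$od, rep(0, 4))
  expect_true("zero_growth" %in% extract_parameters(cv)$qc_flags)

  expect_error(subtract_background(run2, plate_layout(data.frame(
    well_id = c("A1", "Z9"), role = c("sample", "background"),
    combination_id = c("c1", NA)))), "no background")
})

test_that("saturated density is the mean of three reads around the maximum", {
  cv <- growth_curve("k", 0:5, c(0.05, 0.1, 0.4, 0.9, 0.85, 0.86))
  sat <- saturated_density(cv)
  expect_equal(sat$K, (0.4 + 0.9 + 0.85) / 3, tolerance = 1e-12)
  expect_false(sat$edge_max)

  # constant series: maximum ties resolve to the first read, edge flagged
  flat <- growth_curve("f", 0:4, rep(0.5, 5))
  sat_f <- saturated_density(flat)
  expect_equal(sat_f$K, 0.5)
  expect_true(sat_f$edge_max)

  # strictly increasing curve anchors at the final three reads
  inc <- growth_curve("i", 0:4, c(0.1, 0.2, 0.4, 0.8, 1.6))
  sat_i <- saturated_density(inc)
  expect_equal(sat_i$K, mean(c(0.4, 0.8, 1.6)))
  expect_true(sat_i$edge_max)

  expect_error(saturated_density(growth_curve("s", 0:1, c(0.1, 0.2))),
               ">= 3")
})

test_that("the exponential window spans noise floor to f_high * K", {
  cv <- logistic_curve(r = 0.8, K = 1.0, od0 = 0.02)
  K <- saturated_density(cv)$K
  win <- exponential_window(cv, K)
  expect_false(win$zero_growth)
  ods <- cv$od[win$start:win$end]
  expect_true(all(ods >= 0.01 & ods < 0.9 * K))
  expect_true(cv$od[win$end + 1L] >= 0.9 * K)

  # flat curve: empty window, zero growth
  flat <- growth_curve("f", 0:9, rep(0, 10))
  wf <- exponential_window(flat, 0)
  expect_true(wf$zero_growth)
  expect_equal(wf$start, 0L)
})

test_that("a lag-phase spike is excluded from the window", {
  # below floor until t = 6 h, except one spurious read at t = 1 h
  tt <- seq(0, 24, 0.5)
  od <- 1 / (1 + (1 / 0.001 - 1) * exp(-0.6 * (tt - 8)))
  od[3] <- 0.15                       # spike at t = 1 h
  cv <- growth_curve("spk", tt, od)
  K <- saturated_density(cv)$K
  win <- exponential_window(cv, K)
  expect_gt(win$start, 3L)            # window starts after the spike
  expect_true(all(cv$od[win$start:win$end] >= 0.01))
})

test_that("a single-read transient on a flat well is not growth", {
  od <- rep(0.002, 49)
  od[10] <- 0.2                        # lag spike on a non-growing well
  cv <- growth_curve("t", seq(0, 24, 0.5), od)
  p <- extract_parameters(cv)
  expect_equal(p$r, 0)
  expect_true("zero_growth" %in% p$qc_flags)
})

test_that("log slopes follow the stated difference conventions", {
  cv <- growth_curve("d", 0:2, c(0.1, 0.2, 0.4))
  win <- list(start = 1L, end = 3L, zero_growth = FALSE, too_few = FALSE)
  fw <- log_slopes(cv, win, method = "forward")
  expect_equal(fw$slope, c(log(2), log(2)), tolerance = 1e-9)
  ct <- log_slopes(cv, win, method = "central")
  expect_equal(ct$slope, rep(log(2), 3), tolerance = 1e-9)

  # exact exponential: every slope equals the rate, either convention
  tt <- seq(0, 10, 0.5)
  ex <- growth_curve("e", tt, 0.01 * exp(0.5 * tt))
  w2 <- list(start = 1L, end = length(tt), zero_growth = FALSE,
             too_few = FALSE)
  expect_equal(log_slopes(ex, w2, "forward")$slope,
               rep(0.5, length(tt) - 1L), tolerance = 1e-9)

  # half-hour sampling of a doubling
  cv3 <- growth_curve("h", c(0, 0.5), c(0.1, 0.2))
  w3 <- list(start = 1L, end = 2L, zero_growth = FALSE, too_few = FALSE)
  expect_equal(log_slopes(cv3, w3, "forward")$slope, log(2) / 0.5,
               tolerance = 1e-9)
})

test_that("box-plot outlier removal uses linear-interpolation quartiles", {
  sl <- data.frame(slope = c(0.3, 0.4, 0.45, 0.5, 2.5), pos = 1:5)
  kept <- filter_outlier_slopes(sl)         # Q1 = 0.4, Q3 = 0.5, IQR = 0.1
  expect_equal(kept$slope, c(0.3, 0.4, 0.45, 0.5))

  # degenerate IQR: equality sits inside the closed fences
  all_eq <- data.frame(slope = rep(0.5, 4), pos = 1:4)
  expect_equal(nrow(filter_outlier_slopes(all_eq)), 4L)

  # a large negative outlier is removed symmetrically
  neg <- data.frame(slope = c(0.5, 0.5, 0.5, -3), pos = 1:4)
  expect_equal(filter_outlier_slopes(neg)$slope, rep(0.5, 3))

  # compatibility rule drops below-Q1 slopes only
  cfg <- extraction_config(outlier_rule = "below_q1")
  kept_q1 <- filter_outlier_slopes(sl, cfg)
  expect_true(2.5 %in% kept_q1$slope)
  expect_false(0.3 %in% kept_q1$slope)
})

test_that("the growth rate averages the maximal slope with its neighbours", {
  sl <- data.frame(slope = c(0.4, 0.6, 0.55, 0.5), pos = 1:4)
  gr <- growth_rate(sl)
  expect_equal(gr$r, mean(c(0.4, 0.6, 0.55)), tolerance = 1e-12)
  expect_equal(gr$n_slopes_used, 3L)

  # boundary maximum: only one neighbour available
  sl2 <- data.frame(slope = c(0.7, 0.5), pos = 1:2)
  gr2 <- growth_rate(sl2)
  expect_equal(gr2$r, 0.6)
  expect_true(gr2$edge)

  single <- growth_rate(data.frame(slope = 0.7, pos = 1L))
  expect_equal(single$r, 0.7)
  expect_true(single$edge)

  none <- growth_rate(data.frame(slope = numeric(), pos = integer()))
  expect_equal(none$r, 0)
  expect_true(none$zero_growth)
})

test_that("extraction recovers noise-free logistic parameters", {
  cv <- logistic_curve(r = 0.8, K = 1.0, od0 = 0.005)
  p <- extract_parameters(cv)
  expect_lt(abs(p$r - 0.8) / 0.8, 0.10)
  expect_lt(abs(p$K - 1.0), 0.02)

  flat <- growth_curve("z", seq(0, 24, 0.5), rep(0, 49))
  pz <- extract_parameters(flat)
  expect_equal(pz$r, 0)
  expect_true("zero_growth" %in% pz$qc_flags)
})

test_that("exact exponentials are recovered to 1e-9 relative error", {
  for (r in c(0.2, 0.55, 1.1)) for (dt in c(0.25, 0.5, 1)) {
    tt <- seq(0, 14, by = dt)
    cv <- growth_curve("e", tt, 0.004 * exp(r * tt))
    p <- extract_parameters(cv)
    expect_lt(abs(p$r - r) / r, 1e-9)
  }
})

test_that("r is scale-invariant and K scales linearly; background shifts cancel", {
  # on exponential growth the estimate is exactly scale-free; on logistic
  # curves the absolute noise floor shifts the window start by at most a
  # couple of reads, so r moves only marginally while K scales exactly
  tt <- seq(0, 12, 0.5)
  ex <- growth_curve("e", tt, 0.004 * exp(0.5 * tt))
  lam <- 2.7
  ex2 <- growth_curve("e2", tt, lam * ex$od)
  expect_equal(extract_parameters(ex2)$r, extract_parameters(ex)$r,
               tolerance = 1e-9)

  cv <- logistic_curve(r = 0.6, K = 0.8, od0 = 0.004)
  p1 <- extract_parameters(cv)
  p2 <- extract_parameters(growth_curve("s", cv$times, lam * cv$od))
  expect_equal(p2$r, p1$r, tolerance = 0.05)
  expect_equal(p2$K, lam * p1$K, tolerance = 1e-9)

  # adding a constant to background and sample wells leaves curves unchanged
  run <- toy_run(); lay <- toy_layout()
  run2 <- run; run2$od <- run2$od + 0.05
  c1 <- subtract_background(run, lay)
  c2 <- subtract_background(run2, lay)
  expect_equal(c1[[1L]]$od, c2[[1L]]$od, tolerance = 1e-12)
})

test_that("outlier filtering beats the unfiltered estimate on spiked curves", {
  set.seed(42)
  err_full <- err_raw <- numeric(60)
  for (i in 1:60) {
    r <- runif(1, 0.3, 0.8); K <- runif(1, 0.4, 1.2)
    cv <- logistic_curve(r, K, od0 = 0.003, duration = 30)
    win <- exponential_window(cv, saturated_density(cv)$K)
    j <- round((win$start + win$end) / 2)
    od <- cv$od; od[j] <- od[j] + runif(1, 0.1, 0.3)
    spiked <- growth_curve("sp", cv$times, od)
    err_full[i] <- abs(extract_parameters(spiked)$r - r) / r
    err_raw[i] <- abs(extract_parameters(spiked, filter_outliers = FALSE)$r - r) / r
  }
  expect_lt(median(err_full), median(err_raw))
  expect_lt(median(err_full), 0.15)
})

test_that("refinement removes still-rising curves and keeps zero growth", {
  sc <- rk_scenario(n_combinations = 10L, replicates = 2L, noise_sd = 0.002,
                    bio_cv = 0, lag_spike_prob = 0, exp_spike_prob = 0,
                    truncation_prob = 0, seed = 3L)
  sim <- simulate_dataset(sc)
  curves <- unlist(lapply(sim$runs, subtract_background, layout = sim$layout),
                   recursive = FALSE)
  # plant three still-rising curves by hand
  for (i in 1:3) {
    tt <- curves[[i]]$times
    curves[[i]]$od <- 0.002 * exp(0.25 * tt)   # still exponential at 48 h
  }
  rec <- extract_all(curves)
  ref <- refine_dataset(rec, curves)
  expect_setequal(ref$removed$curve_id,
                  vapply(curves[1:3], `[[`, "", "curve_id"))
  expect_equal(ref$removed$reason, rep("incomplete", 3))

  # all-complete set passes through unchanged
  ref2 <- refine_dataset(extract_all(curves[-(1:3)]), curves[-(1:3)])
  expect_equal(nrow(ref2$removed), 0L)

  # zero-growth curves are retained with r = 0
  flat <- lapply(1:3, function(i)
    growth_curve(paste0("z", i), seq(0, 24, 0.5), rep(0, 49),
                 combination_id = "cz"))
  refz <- refine_dataset(extract_all(flat), flat)
  expect_equal(nrow(refz$records), 3L)
  expect_equal(refz$records$r, rep(0, 3))
})

test_that("refinement never removes a curve whose final slope is at tolerance", {
  cfg <- extraction_config()
  set.seed(9)
  for (i in 1:25) {
    cv <- logistic_curve(r = runif(1, 0.3, 0.8), K = runif(1, 0.3, 1.2),
                         od0 = 0.003, duration = 30, id = paste0("c", i))
    n <- length(cv$od)
    idx <- (n - cfg$plateau_window + 1L):n
    fin <- mean(diff(log(cv$od[idx])) / diff(cv$times[idx]))
    ref <- refine_dataset(extract_all(list(cv)), list(cv), cfg)
    if (fin <= cfg$plateau_slope_tol)
      expect_equal(nrow(ref$removed), 0L)
  }
})

test_that("aggregation reports replicate means and standard errors", {
  rec <- growth_records(data.frame(
    curve_id = c("a1", "a2", "b1", "c1", "c2"),
    combination_id = c("A", "A", "B", "C", "C"),
    replicate_index = c(1L, 2L, 1L, 1L, 2L),
    r = c(0.5, 0.7, 0.4, 0.3, 0.3), K = c(1, 1.2, 0.8, 0.6, 0.6),
    qc_flags = ""))
  agg <- aggregate_combinations(rec, n_min = 2L)
  a <- agg[agg$combination_id == "A", ]
  expect_equal(a$mean_r, 0.6)
  expect_equal(a$se_r, 0.1)                      # two-point mean / SE
  expect_true(is.na(agg$se_r[agg$combination_id == "B"]))
  expect_true(agg$low_n[agg$combination_id == "B"])
  expect_equal(agg$se_K[agg$combination_id == "C"], 0)  # identical replicates
})
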