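test_that("best and worst paths trace the extreme leaves", {
  tr <- fit_tree(cbind(x = c(0, 0, 2, 2)), c(0, 0, 10, 10),
                 max_depth = 1L, min_leaf = 1L)
  p <- best_worst_paths(tr)
  expect_equal(p$best$leaf_mean, 10)
  expect_equal(p$best$constraints$direction, ">")
  expect_equal(p$best$constraints$threshold_log10, 1)
  expect_equal(p$worst$leaf_mean, 0)
  expect_equal(p$worst$constraints$direction, "<=")

  # depth-0 tree: both paths empty
  tr0 <- fit_tree(cbind(x = 1:4), rep(2, 4), max_depth = 0L)
  p0 <- best_worst_paths(tr0)
  expect_equal(nrow(p0$best$constraints), 0L)
  expect_equal(nrow(p0$worst$constraints), 0L)

  # planted two-level structure reproduces its cell constraints
  set.seed(13)
  X <- matrix(runif(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- ifelse(X[, 1] <= 0.5 & X[, 2] > 0.5, 5, 1)
  tr2 <- fit_tree(X, y, max_depth = 2L, min_leaf = 5L)
  b <- best_worst_paths(tr2)$best
  expect_equal(b$leaf_mean, 5)
  cons <- b$constraints
  expect_setequal(cons$component, c("a", "b"))
  expect_equal(cons$direction[cons$component == "a"], "<=")
  expect_equal(cons$direction[cons$component == "b"], ">")
})

test_that("optimal intervals back-transform thresholds and intersect bounds", {
  ranges <- data.frame(component = c("NH4", "glucose"),
                       min_mM = c(20, 2), max_mM = c(400, 200))
  path <- structure(list(constraints = data.frame(
    component = c("NH4", "NH4"), direction = c(">", "<="),
    threshold_log10 = c(1.8007, 2.4510),
    threshold_mM = 10^c(1.8007, 2.4510), stringsAsFactors = FALSE),
    leaf_mean = 0.8, leaf_n = 100), class = "leaf_path")
  iv <- optimal_intervals(path, ranges)
  expect_equal(iv$lower_mM, 63.2, tolerance = 1e-3)
  expect_equal(iv$upper_mM, 282.4, tolerance = 1e-3)

  # absent component falls back to the full design range
  iv2 <- optimal_intervals(path, ranges, components = c("NH4", "glucose"))
  glc <- iv2[iv2$component == "glucose", ]
  expect_equal(c(glc$lower_mM, glc$upper_mM), c(2, 200))
  expect_false(glc$upper_bounded)

  # two upper bounds intersect to the tighter one
  path$constraints <- data.frame(
    component = "NH4", direction = c("<=", "<="),
    threshold_log10 = c(2, 1.5), threshold_mM = 10^c(2, 1.5))
  iv3 <- optimal_intervals(path, ranges)
  expect_equal(iv3$upper_mM, 10^1.5, tolerance = 1e-9)
})

test_that("mechanism calls separate overlapping and disjoint optima", {
  rate <- data.frame(component = c("glucose", "NH4", "Mg"),
                     lower_mM = c(2, 63.2, 2), upper_mM = c(63.2, 282.8, 22.4),
                     lower_bounded = c(FALSE, TRUE, FALSE),
                     upper_bounded = TRUE)
  dens <- data.frame(component = c("glucose", "NH4", "Fe"),
                     lower_mM = c(2, 20, 0.001), upper_mM = c(63.2, 63.2, 1),
                     lower_bounded = FALSE, upper_bounded = TRUE)
  mech <- classify_mechanism(rate, dens)
  expect_equal(call_of(mech, "glucose"), "uniform")
  # NH4 intervals touch at 63.2 only: disjoint interiors, a trade-off
  expect_equal(call_of(mech, "NH4"), "trade_off")
  expect_equal(call_of(mech, "Mg"), "unshared")
  expect_equal(call_of(mech, "Fe"), "unshared")

  # identical intervals are uniform; symmetry up to labels
  same <- classify_mechanism(rate, rate)
  expect_true(all(same$call == "uniform"))
  swapped <- classify_mechanism(dens, rate)
  expect_equal(sort(paste(swapped$component, swapped$call)),
               sort(paste(mech$component, mech$call)))
})

test_that("spearman_rk matches rank correlation with t-approximate p", {
  rec <- growth_records(data.frame(
    curve_id = paste0("c", 1:6), combination_id = paste0("m", 1:6),
    replicate_index = 1L, r = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    K = c(0.2, 0.3, 0.5, 0.6, 0.8, 0.9), qc_flags = ""))
  s <- spearman_rk(rec, "curve")
  expect_equal(s$rho, 1)
  expect_equal(s$p, 0)

  rec$K <- rev(rec$K)
  expect_equal(spearman_rk(growth_records(rec), "curve")$rho, -1)

  # seeded bivariate sample: rho near the construction's population value
  set.seed(21)
  n <- 500
  z <- rnorm(n); r <- pmax(0, z + rnorm(n)); K <- pmax(0, z + rnorm(n))
  rec2 <- growth_records(data.frame(
    curve_id = paste0("c", 1:n), combination_id = paste0("m", 1:n),
    replicate_index = 1L, r = r, K = K, qc_flags = ""))
  s2 <- spearman_rk(rec2, "curve")
  pop <- 6 / pi * asin(0.5 / 2)       # rank correlation of rho = .5 gaussians
  expect_lt(abs(s2$rho - pop), 0.05)
  ct <- suppressWarnings(cor.test(r, K, method = "spearman"))
  expect_equal(s2$rho, unname(ct$estimate), tolerance = 1e-12)

  # constant column: undefined, reported missing
  rec3 <- rec
  rec3$K <- 1
  expect_true(is.na(spearman_rk(growth_records(rec3), "curve")$rho))
})

test_that("the OLS baseline recovers exact linear structure and flags collinearity", {
  set.seed(31)
  X <- matrix(rnorm(17 * 40), ncol = 17)
  colnames(X) <- paste0("f", 1:17)
  y <- 3 * X[, 1]
  fit <- suppressWarnings(regression_baseline(X[, 1:15], y))
  co <- fit$coefficients
  expect_equal(co$estimate[co$component == "f1"], 3, tolerance = 1e-9)
  expect_true(all(abs(co$estimate[!co$component %in% c("f1", "(Intercept)")])
                  < 1e-9))

  # duplicated feature columns make the design rank-deficient
  Xd <- cbind(X[, 1:5], dup = X[, 1])
  expect_error(regression_baseline(Xd, y), "collinear")
  fit2 <- suppressWarnings(regression_baseline(Xd, y, drop_aliased = TRUE))
  expect_true("dup" %in% fit2$dropped)

  const <- cbind(X[, 1:5], flatcol = 1)
  expect_error(regression_baseline(const, y), "constant")
})

test_that("regression misses the non-monotone NH4 effect that the tree finds", {
  d <- default_records(1L)
  X <- d$features[match(d$records$combination_id, rownames(d$features)), ,
                  drop = FALSE]
  y <- d$records$r
  fit <- regression_baseline(X, y, drop_aliased = TRUE)
  tr <- fit_tree(X, y, max_depth = 4L, min_leaf = 20L)
  expect_equal(tr$root$feature, "NH4")
  # the linear model cannot rank the window-shaped NH4 effect first
  co <- fit$coefficients[fit$coefficients$component != "(Intercept)", ]
  expect_false(co$component[which.max(abs(co$t))] == "NH4")
})

test_that("the pipeline is deterministic and validates its inputs", {
  sc <- rk_scenario(n_combinations = 12L, replicates = 3L, seed = 8L)
  sim <- simulate_dataset(sc)
  rep1 <- run_pipeline(sim$runs, sim$layout, sim$media, depth = 2L,
                       seed = 8L, stability_repeats = 1L, min_leaf = 5L)
  rep2 <- run_pipeline(sim$runs, sim$layout, sim$media, depth = 2L,
                       seed = 8L, stability_repeats = 1L, min_leaf = 5L)
  expect_identical(report_json(rep1), report_json(rep2))
  expect_s3_class(rep1$rate_tree, "rk_tree")
  expect_true(all(c("r", "K") %in% names(rep1$cv)))
  expect_error(run_pipeline(sim$runs, sim$layout, sim$media[0, ]),
               "empty media")
})
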