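# shared builders and oracles for the test suite

# toy 3-timepoint, 2-well plate run (plus one background well)
toy_run <- function() {
  od <- cbind(B1 = c(0.08, 0.08, 0.08),
              A1 = c(0.18, 0.28, 0.48),
              A2 = c(0.13, 0.18, 0.28))
  plate_run("toy", c(0, 0.5, 1), od)
}

toy_layout <- function() {
  plate_layout(data.frame(
    well_id = c("B1", "A1", "A2"),
    role = c("background", "sample", "sample"),
    combination_id = c(NA, "comboA", "comboA"),
    stringsAsFactors = FALSE))
}

toy_media <- function() {
  df <- data.frame(combination_id = "comboA", glucose = 22.4,
                   `(NH4)2SO4` = 31.6, K2HPO4 = 62.5, KH2PO4 = 37.5,
                   MgSO4 = 1, thiamine_HCl = 0.003, FeSO4 = 0.0045,
                   NaCl = 0, leucine = 0, histidine = 0,
                   check.names = FALSE, stringsAsFactors = FALSE)
  media_table(df)
}

# noise-free logistic growth curve (background already removed)
logistic_curve <- function(r, K, od0 = 0.005, interval = 0.5, duration = 24,
                           lag = 0, id = "lg") {
  tt <- seq(0, duration, by = interval)
  od <- K / (1 + ((K - od0) / od0) * exp(-r * (tt - lag)))
  growth_curve(id, tt, od)
}

# brute-force root-split oracle: enumerate every (feature, midpoint)
# candidate and minimize the summed child squared error directly
brute_force_root <- function(X, y, min_leaf = 5L) {
  X <- as.matrix(X)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (i in seq_len(length(vals) - 1L)) {
      thr <- (vals[i] + vals[i + 1L]) / 2
      lhs <- X[, j] <= thr
      if (sum(lhs) < min_leaf || sum(!lhs) < min_leaf) next
      cost <- sum((y[lhs] - mean(y[lhs]))^2) +
        sum((y[!lhs] - mean(y[!lhs]))^2)
      if (is.null(best) || cost < best$cost - 1e-12 * max(1, abs(best$cost)))
        best <- list(j = j, threshold = thr, cost = cost)
    }
  }
  best
}

# small synthetic dataset cache (simulation + extraction are the slow parts)
.sim_cache <- new.env(parent = emptyenv())
default_records <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- simulate_dataset(rk_scenario(seed = seed))
  curves <- unlist(lapply(sim$runs, subtract_background, layout = sim$layout),
                   recursive = FALSE)
  rec <- refine_dataset(extract_all(curves))$records
  fm <- log_features(expand_to_ions(sim$media), drop_all_zero = TRUE)
  out <- list(records = rec, media = sim$media, features = fm,
              well_truth = sim$well_truth, truth = sim$truth)
  .sim_cache[[key]] <- out
  out
}

# tree fitting + mechanism classification for one cached dataset
mechanism_calls <- function(seed) {
  d <- default_records(seed)
  X <- d$features[match(d$records$combination_id, rownames(d$features)), ,
                  drop = FALSE]
  rt <- fit_tree(X, d$records$r, max_depth = 4L, min_leaf = 20L)
  dt <- fit_tree(X, d$records$K, max_depth = 4L, min_leaf = 20L)
  ranges <- design_ranges(d$media)
  iv_r <- optimal_intervals(best_worst_paths(rt)$best, ranges)
  iv_K <- optimal_intervals(best_worst_paths(dt)$best, ranges)
  classify_mechanism(iv_r, iv_K)
}

call_of <- function(mech, cmp) {
  if (cmp %in% mech$component) mech$call[mech$component == cmp] else "absent"
}
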