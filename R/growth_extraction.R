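# Automated growth-parameter extraction: background subtraction, saturated
# density (K), and the four-step growth-rate (r) calculation with
# exponential-window selection and box-plot outlier removal.

#' Extraction configuration
#'
#' Tunable parameters of the growth-parameter extraction.
#'
#' @param noise_floor OD600 level below which readings are treated as
#'   detector noise (default 0.01). The exponential window starts at the
#'   last crossing of this floor before sustained growth.
#' @param f_high Fraction of K at which the exponential window ends
#'   (default 0.9): the window is the contiguous run of readings below
#'   `f_high * K`.
#' @param plateau_slope_tol Mean log-slope (h^-1) of the final
#'   `plateau_window` reads above which a curve that has cleared the noise
#'   floor is still rising at run end, i.e. incomplete (default 0.02).
#' @param plateau_window Number of final reads used for the plateau test
#'   (default 5).
#' @param outlier_rule `"tukey"` (symmetric box-plot fences, default) or
#'   `"below_q1"` (discard slopes below the first quartile only).
#' @param tukey_k Fence multiplier for the Tukey rule (default 1.5).
#' @param min_window_points Minimum exponential-window size before the
#'   fallback to the longest rising run is used (default 4).
#' @param slope_method `"central"` (gradient convention, default) or
#'   `"forward"`; see [log_slopes()].
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(noise_floor = 0.01, f_high = 0.9,
                              plateau_slope_tol = 0.02, plateau_window = 5L,
                              outlier_rule = c("tukey", "below_q1"),
                              tukey_k = 1.5, min_window_points = 4L,
                              slope_method = c("central", "forward")) {
  outlier_rule <- match.arg(outlier_rule)
  slope_method <- match.arg(slope_method)
  stopifnot(noise_floor > 0, f_high > 0, f_high < 1,
            plateau_slope_tol >= 0, plateau_window >= 2L,
            tukey_k >= 0, min_window_points >= 2L)
  structure(list(noise_floor = noise_floor, f_high = f_high,
                 plateau_slope_tol = plateau_slope_tol,
                 plateau_window = as.integer(plateau_window),
                 outlier_rule = outlier_rule, tukey_k = tukey_k,
                 min_window_points = as.integer(min_window_points),
                 slope_method = slope_method),
            class = "extraction_config")
}

#' Construct a background-corrected growth curve
#'
#' @param curve_id Curve identifier.
#' @param times Timepoints in hours, strictly increasing.
#' @param od Background-corrected OD600 readings (may be slightly negative
#'   after correction; they are only floored at log time).
#' @param combination_id,well_id,run_id Optional provenance.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(curve_id, times, od, combination_id = NA_character_,
                         well_id = NA_character_, run_id = NA_character_) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od))) stop("od must be finite")
  structure(list(curve_id = as.character(curve_id), times = times, od = od,
                 combination_id = as.character(combination_id),
                 well_id = as.character(well_id),
                 run_id = as.character(run_id)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("<growth_curve> ", x$curve_id, ": ", length(x$times), " reads, max OD ",
      signif(max(x$od), 4), "\n", sep = "")
  invisible(x)
}

#' Subtract the optical background from sample wells
#'
#' The optical background at each timepoint is the mean OD600 of the
#' medium-only (background) wells of the same run; it is subtracted from
#' every sample well, yielding one [growth_curve()] per sample well.
#'
#' @param run A [plate_run()].
#' @param layout A [plate_layout()]; if it has a `run_id` column only rows
#'   matching `run$run_id` are used.
#' @return List of [growth_curve()] objects.
#' @export
subtract_background <- function(run, layout) {
  stopifnot(inherits(run, "plate_run"))
  lay <- layout
  if ("run_id" %in% names(lay))
    lay <- lay[lay$run_id == run$run_id, , drop = FALSE]
  bg_wells <- intersect(lay$well_id[lay$role == "background"],
                        colnames(run$od))
  if (!length(bg_wells))
    stop("no background wells for run ", run$run_id)
  bg <- rowMeans(run$od[, bg_wells, drop = FALSE], na.rm = TRUE)
  samp <- lay[lay$role == "sample" & lay$well_id %in% colnames(run$od), ,
              drop = FALSE]
  lapply(seq_len(nrow(samp)), function(i) {
    w <- samp$well_id[i]
    od <- run$od[, w] - bg
    keep <- !is.na(od)          # trailing gap truncation
    growth_curve(curve_id = paste(run$run_id, w, sep = "."),
                 times = run$times[keep], od = od[keep],
                 combination_id = samp$combination_id[i],
                 well_id = w, run_id = run$run_id)
  })
}

#' Saturated density K
#'
#' K is the mean of three continuous readings that include the maximum
#' corrected OD600. The window is centered on the (first) maximum; when the
#' maximum sits at the first or last read, the three reads anchored at that
#' edge are used and `edge_max` is flagged.
#'
#' @param curve A [growth_curve()] with at least 3 readings.
#' @return List with elements `K` and `edge_max`.
#' @export
saturated_density <- function(curve) {
  od <- curve$od
  n <- length(od)
  if (n < 3L) stop("saturated_density needs >= 3 readings")
  m <- which.max(od)
  edge <- m == 1L || m == n
  idx <- if (m == 1L) 1:3 else if (m == n) (n - 2L):n else (m - 1L):(m + 1L)
  list(K = mean(od[idx]), edge_max = edge)
}

#' Step 1: locate the exponential window
#'
#' The window is the contiguous run of readings that ends just before the
#' curve reaches `f_high * K` and starts after the last crossing of the
#' noise floor before that sustained rise. Anchoring the start at the last
#' floor crossing excludes isolated lag-phase spikes, which would otherwise
#' contribute spurious maximal slopes. If the window has fewer than
#' `min_window_points` readings the longest rising run above the floor is
#' used instead and `too_few` is flagged.
#'
#' @param curve A [growth_curve()].
#' @param K Saturated density from [saturated_density()].
#' @param cfg An [extraction_config()].
#' @return List with `start`, `end` (inclusive 1-based indices; both 0 for
#'   an empty window), `zero_growth` and `too_few` flags.
#' @export
exponential_window <- function(curve, K, cfg = extraction_config()) {
  od <- curve$od
  if (max(od) < cfg$noise_floor)
    return(list(start = 0L, end = 0L, zero_growth = TRUE, too_few = FALSE))
  # sustained-growth guard: a single-read transient (lag-phase spike on an
  # otherwise flat well) is not growth — the curve must hold a level near
  # its maximum for at least two consecutive reads
  hi_reads <- od >= 0.5 * max(K, cfg$noise_floor)
  if (!any(hi_reads & c(hi_reads[-1L], FALSE)))
    return(list(start = 0L, end = 0L, zero_growth = TRUE, too_few = FALSE))
  hi <- which(od >= cfg$f_high * K)
  end_excl <- if (length(hi)) hi[1L] else length(od) + 1L
  below <- which(od[seq_len(end_excl - 1L)] < cfg$noise_floor)
  start <- if (length(below)) max(below) + 1L else 1L
  end <- end_excl - 1L
  too_few <- (end - start + 1L) < cfg$min_window_points
  if (too_few) {
    rr <- longest_rising_run(od, cfg$noise_floor)
    if (!is.null(rr) && (rr[2L] - rr[1L]) > (end - start)) {
      start <- rr[1L]; end <- rr[2L]
    }
  }
  if (end < start)
    return(list(start = 0L, end = 0L, zero_growth = FALSE, too_few = TRUE))
  list(start = start, end = end, zero_growth = FALSE, too_few = too_few)
}

# longest run of consecutive indices with od above floor and rising
longest_rising_run <- function(od, floor_) {
  ok <- od >= floor_
  rising <- c(FALSE, diff(od) > 0) & ok & c(FALSE, ok[-length(ok)])
  best <- NULL; len_best <- 0L; i <- 1L
  n <- length(od)
  while (i <= n) {
    if (rising[i]) {
      j <- i
      while (j < n && rising[j + 1L]) j <- j + 1L
      if ((j - i + 2L) > len_best) {   # run includes the read before the rise
        best <- c(i - 1L, j); len_best <- j - i + 2L
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

#' Step 2: log-slopes of neighbouring readings
#'
#' Slopes of the natural log of OD600 per hour inside the window. The
#' default `central` method is the numerical-gradient convention (central
#' differences at interior points, one-sided at the two window edges; one
#' slope per reading), which averages read noise over two sampling
#' intervals. The `forward` method is the plain neighbouring-pair
#' difference (one slope per pair). Non-positive readings inside the
#' window are dropped with a warning (slopes bridge the gap).
#'
#' @param curve A [growth_curve()].
#' @param window Window from [exponential_window()].
#' @param method `"central"` (gradient, default) or `"forward"`.
#' @return Data frame with columns `slope` (h^-1) and `pos` (reading index
#'   the slope is attached to: the reading itself for `central`, the
#'   left-hand reading for `forward`), in time order. Zero rows when the
#'   window has fewer than two usable points.
#' @export
log_slopes <- function(curve, window, method = c("central", "forward")) {
  method <- match.arg(method)
  if (window$start == 0L)
    return(data.frame(slope = numeric(), pos = integer()))
  idx <- window$start:window$end
  pos_ok <- idx[curve$od[idx] > 0]
  if (length(pos_ok) < length(idx))
    warning("dropping ", length(idx) - length(pos_ok),
            " non-positive reading(s) inside the exponential window of ",
            curve$curve_id)
  if (length(pos_ok) < 2L)
    return(data.frame(slope = numeric(), pos = integer()))
  lo <- log(curve$od[pos_ok])
  tt <- curve$times[pos_ok]
  if (method == "forward")
    return(data.frame(slope = diff(lo) / diff(tt),
                      pos = pos_ok[-length(pos_ok)]))
  m <- length(lo)
  if (m == 2L)
    return(data.frame(slope = rep((lo[2L] - lo[1L]) / (tt[2L] - tt[1L]), 2L),
                      pos = pos_ok))
  inner <- 2:(m - 1L)
  data.frame(
    slope = c((lo[2L] - lo[1L]) / (tt[2L] - tt[1L]),
              (lo[inner + 1L] - lo[inner - 1L]) / (tt[inner + 1L] - tt[inner - 1L]),
              (lo[m] - lo[m - 1L]) / (tt[m] - tt[m - 1L])),
    pos = pos_ok)
}

#' Step 3: remove outlier slopes
#'
#' Box-plot based outlier removal. The default `tukey` rule keeps slopes
#' inside the closed fences `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles by
#' linear interpolation of order statistics; the `below_q1` compatibility
#' rule discards slopes strictly below Q1 only. Positions are preserved so
#' neighbour averaging can use surviving slopes. With fewer than 3 slopes
#' nothing is filtered.
#'
#' @param slopes Data frame from [log_slopes()].
#' @param cfg An [extraction_config()].
#' @return The surviving rows of `slopes`.
#' @export
filter_outlier_slopes <- function(slopes, cfg = extraction_config()) {
  s <- slopes$slope
  if (length(s) < 3L) return(slopes)
  q <- stats::quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
  keep <- if (cfg$outlier_rule == "tukey") {
    iqr <- q[2L] - q[1L]
    s >= q[1L] - cfg$tukey_k * iqr & s <= q[2L] + cfg$tukey_k * iqr
  } else {
    s >= q[1L]
  }
  slopes[keep, , drop = FALSE]
}

#' Step 4: growth rate from the maximal surviving slope
#'
#' r is the mean of the maximal surviving slope and its nearest surviving
#' neighbours in time order (one on each side; fewer at a boundary),
#' floored at 0.
#'
#' @param slopes Data frame of surviving slopes (columns `slope`, `pos`).
#' @return List with `r`, `n_slopes_used`, and flags `zero_growth`
#'   (no slopes) and `edge` (maximum at a boundary of the surviving list).
#' @export
growth_rate <- function(slopes) {
  s <- slopes$slope
  if (!length(s))
    return(list(r = 0, n_slopes_used = 0L, zero_growth = TRUE, edge = FALSE))
  i <- which.max(s)
  picks <- c(if (i > 1L) i - 1L, i, if (i < length(s)) i + 1L)
  list(r = max(0, mean(s[picks])),
       n_slopes_used = length(picks),
       zero_growth = FALSE,
       edge = length(picks) < 3L)
}

#' Extract (r, K) and QC flags from one growth curve
#'
#' Chains [saturated_density()], [exponential_window()], [log_slopes()],
#' [filter_outlier_slopes()] and [growth_rate()].
#'
#' QC flags: `zero_growth` (curve never clears the noise floor; r = 0),
#' `edge_max` (K window anchored at an edge), `too_few_slopes`,
#' `incomplete` (still rising over the final plateau window).
#'
#' @param curve A [growth_curve()].
#' @param cfg An [extraction_config()].
#' @param filter_outliers Disable step 3 with `FALSE` (for ablation
#'   comparisons).
#' @return List of class `growth_parameters`: `r`, `K`, `window`,
#'   `n_slopes_used`, `qc_flags` (character vector).
#' @export
extract_parameters <- function(curve, cfg = extraction_config(),
                               filter_outliers = TRUE) {
  sat <- saturated_density(curve)
  win <- exponential_window(curve, sat$K, cfg)
  flags <- character()
  if (sat$edge_max) flags <- c(flags, "edge_max")
  if (win$zero_growth) {
    r <- 0; n_used <- 0L
    flags <- c(flags, "zero_growth")
  } else {
    sl <- log_slopes(curve, win, method = cfg$slope_method)
    if (filter_outliers) sl <- filter_outlier_slopes(sl, cfg)
    gr <- growth_rate(sl)
    r <- gr$r; n_used <- gr$n_slopes_used
    if (gr$zero_growth) flags <- c(flags, "zero_growth")
    if (win$too_few || nrow(sl) < 3L) flags <- c(flags, "too_few_slopes")
  }
  if (is_incomplete(curve, cfg)) flags <- c(flags, "incomplete")
  structure(list(r = r, K = max(0, sat$K),
                 window = c(start = win$start, end = win$end),
                 n_slopes_used = n_used, qc_flags = unique(flags)),
            class = "growth_parameters")
}

# still rising at run end: mean log-slope over the final plateau_window
# reads exceeds plateau_slope_tol. Only curves that grew appreciably
# (top-3 mean >= 2x noise floor) are eligible: in a flat well the final
# window is pure read noise and its log-slope is meaningless.
is_incomplete <- function(curve, cfg) {
  od <- curve$od
  if (max(od) < cfg$noise_floor) return(FALSE)
  if (saturated_density(curve)$K < 2 * cfg$noise_floor) return(FALSE)
  n <- length(od)
  idx <- seq.int(max(1L, n - cfg$plateau_window + 1L), n)
  idx <- idx[od[idx] > 0]
  if (length(idx) < 2L) return(FALSE)
  slopes <- diff(log(od[idx])) / diff(curve$times[idx])
  mean(slopes) > cfg$plateau_slope_tol
}

#' Extract growth records for a list of curves
#'
#' @param curves List of [growth_curve()] objects.
#' @param cfg An [extraction_config()].
#' @param filter_outliers Passed to [extract_parameters()].
#' @return A [growth_records()] table (replicate_index assigned in curve
#'   order within each combination).
#' @export
extract_all <- function(curves, cfg = extraction_config(),
                        filter_outliers = TRUE) {
  pars <- lapply(curves, extract_parameters, cfg = cfg,
                 filter_outliers = filter_outliers)
  df <- data.frame(
    curve_id = vapply(curves, `[[`, "", "curve_id"),
    combination_id = vapply(curves, `[[`, "", "combination_id"),
    replicate_index = NA_integer_,
    r = vapply(pars, `[[`, 0, "r"),
    K = vapply(pars, `[[`, 0, "K"),
    qc_flags = vapply(pars, function(p) paste(p$qc_flags, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  df$K <- pmax(df$K, 0)
  df$replicate_index <- stats::ave(seq_len(nrow(df)), df$combination_id,
                                   FUN = seq_along)
  growth_records(df)
}

#' Refine a growth-record table
#'
#' Removes curves flagged `incomplete` (still rising at the end of the
#' run). Zero-growth curves are retained: r = 0 is information, and
#' dropping them would bias the trees' zero-growth leaves.
#'
#' @param records A [growth_records()] table.
#' @param curves Optional list of [growth_curve()] objects matching
#'   `records$curve_id`; when given, the incompleteness test is recomputed
#'   from the curves, otherwise the recorded `incomplete` flag is used.
#' @param cfg An [extraction_config()].
#' @return List with `records` (refined table) and `removed` (data frame
#'   `curve_id`, `reason`).
#' @export
refine_dataset <- function(records, curves = NULL,
                           cfg = extraction_config()) {
  if (!is.null(curves)) {
    ids <- vapply(curves, `[[`, "", "curve_id")
    inc <- vapply(curves, is_incomplete, NA, cfg = cfg)
    drop <- records$curve_id %in% ids[inc]
  } else {
    drop <- grepl("\\bincomplete\\b", records$qc_flags)
  }
  removed <- data.frame(curve_id = records$curve_id[drop],
                        reason = rep("incomplete", sum(drop)),
                        stringsAsFactors = FALSE)
  kept <- records[!drop, , drop = FALSE]
  list(records = growth_records(kept), removed = removed)
}

#' Aggregate growth records per combination
#'
#' Arithmetic mean and standard error of r and K per combination.
#' Single-replicate combinations get `NA` standard errors; combinations
#' with fewer than `n_min` replicates are flagged.
#'
#' @param records A [growth_records()] table.
#' @param n_min Low-replicate threshold (default 3).
#' @return Data frame: `combination_id`, `n`, `mean_r`, `se_r`, `mean_K`,
#'   `se_K`, `low_n`.
#' @export
aggregate_combinations <- function(records, n_min = 3L) {
  sp <- split(records, records$combination_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    n <- nrow(g)
    data.frame(combination_id = g$combination_id[1L], n = n,
               mean_r = mean(g$r),
               se_r = if (n > 1L) stats::sd(g$r) / sqrt(n) else NA_real_,
               mean_K = mean(g$K),
               se_K = if (n > 1L) stats::sd(g$K) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$low_n <- out$n < n_min
  rownames(out) <- NULL
  out
}
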