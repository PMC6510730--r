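# Synthetic plate-scale datasets with planted decision structure:
# log-gridded media designs, piecewise (r*, K*) response rules with
# trade-off and uniform mechanisms, logistic growth curves, detector
# noise, and realistic artifacts (lag/exponential spikes, still-rising
# truncation).

#' Synthetic study scenario
#'
#' Defines the design and measurement conditions of a synthetic dataset.
#' The defaults emulate a high-throughput growth assay: 225 combinations
#' drawn from a log-spaced factorial over six varied compounds, 5
#' replicate wells each, 0.5-h reads for 48 h, additive read noise of
#' 0.005 OD, and a 5% rate for each artifact class. The varied grids are
#' placed so that geometric means of adjacent levels land on the decision
#' boundaries of the planted response rules (e.g. NH4 63.2 and 282.8 mM,
#' Mg 22.4 mM, glucose 63.2 mM).
#'
#' @param varied Named list: compound -> increasing vector of grid levels
#'   (mM).
#' @param fixed Named numeric: constant compounds (mM). The phosphate pair
#'   is held at the 5:3 buffering ratio.
#' @param n_combinations Number of combinations C (<= product of grid
#'   sizes; equality gives the full factorial).
#' @param replicates Replicate wells N per combination.
#' @param interval_h,duration_h Read interval and total run length (h).
#' @param noise_sd Additive Gaussian read noise (OD units).
#' @param od0 Inoculum density (OD units above background).
#' @param background Optical background of plate + medium (OD units).
#' @param lag_range Per-well lag time drawn uniformly from this range (h).
#' @param bio_cv Biological well-to-well variability: each replicate's
#'   (r*, K*) are multiplied by independent lognormal factors with this
#'   coefficient of variation (default 0.18). This is what makes
#'   replicate means less noisy than individual curves.
#' @param bio_rho Correlation of the per-well log factors for r and K
#'   (default -0.85): a replicate that happens to grow faster than its
#'   siblings tends to saturate lower, the resource-allocation trade-off
#'   acting at the well level.
#' @param lag_spike_prob,exp_spike_prob,truncation_prob Per-well artifact
#'   probabilities (mutually exclusive draws).
#' @param so4_from_nh4_only Use the confounded-ion expansion of
#'   [ion_expansion()] when building features from this design.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return List of class `rk_scenario`.
#' @export
rk_scenario <- function(varied = NULL, fixed = NULL, n_combinations = 225L,
                        replicates = 5L, interval_h = 0.5, duration_h = 48,
                        noise_sd = 0.005, od0 = 1e-3, background = 0.08,
                        lag_range = c(1, 3), bio_cv = 0.18, bio_rho = -0.85,
                        lag_spike_prob = 0.05,
                        exp_spike_prob = 0.05, truncation_prob = 0.05,
                        so4_from_nh4_only = FALSE, seed = 1L) {
  if (is.null(varied))
    varied <- list(
      glucose = c(2, 20, 200),
      `(NH4)2SO4` = c(10, 100, 200),     # NH4: 20, 200, 400 mM
      MgSO4 = c(5, 100),                 # geometric mean 22.36 mM
      FeSO4 = c(0.001, 0.1, 10),
      NaCl = c(1, 10, 100),
      thiamine_HCl = c(0.0015, 0.015))
  if (is.null(fixed))
    fixed <- c(K2HPO4 = 62.5, KH2PO4 = 37.5, leucine = 0.4, histidine = 0.2)
  stopifnot(all(names(varied) %in% rk_compounds()),
            all(names(fixed) %in% rk_compounds()),
            !anyDuplicated(c(names(varied), names(fixed))),
            all(unlist(varied) > 0), all(fixed >= 0),
            n_combinations >= 1L, replicates >= 1L,
            interval_h > 0, duration_h > interval_h, noise_sd >= 0,
            od0 > 0, background >= 0, bio_cv >= 0,
            bio_rho >= -1, bio_rho <= 1,
            all(c(lag_spike_prob, exp_spike_prob, truncation_prob) >= 0),
            lag_spike_prob + exp_spike_prob + truncation_prob <= 1)
  structure(list(varied = varied, fixed = fixed,
                 n_combinations = as.integer(n_combinations),
                 replicates = as.integer(replicates),
                 interval_h = interval_h, duration_h = duration_h,
                 noise_sd = noise_sd, od0 = od0, background = background,
                 lag_range = lag_range, bio_cv = bio_cv, bio_rho = bio_rho,
                 lag_spike_prob = lag_spike_prob,
                 exp_spike_prob = exp_spike_prob,
                 truncation_prob = truncation_prob,
                 so4_from_nh4_only = so4_from_nh4_only,
                 seed = as.integer(seed)),
            class = "rk_scenario")
}

#' Planted ground-truth response rules
#'
#' Piecewise-constant window rules on the ion profile. The growth rate is
#' `r_max * g_NH4 * g_Mg * g_glc`: the optimal NH4 window is
#' (63.2, 282.8] mM (low NH4 reduces the rate, excess NH4 means zero
#' growth), the optimal Mg window is (0.1, 22.4] mM (depletion below
#' 0.1 mM means zero growth, excess reduces the rate), and glucose
#' prefers <= 63.2 mM. The density is
#' `K_max * h_NH4 * h_Fe * h_Mg * h_glc * h_thi * h_Na` with *disjoint*
#' NH4/Mg optima (NH4 <= 63.2 mM, Mg > 22.4 mM), iron toxic above 1 mM,
#' the *same* glucose preference (<= 63.2 mM), and mild yield costs of
#' thiamine limitation and high-salt osmotic stress — so NH4 and Mg are
#' planted trade-off chemicals and glucose a uniform one, with the shared
#' glucose effect giving growing wells the weak positive r-K coupling
#' seen in real growth landscapes. A well that cannot grow (r* = 0) has
#' K* = 0.
#'
#' @param r_max Maximal growth rate (h^-1, default 0.8).
#' @param K_max Maximal saturated density (OD units, default 1.2).
#' @return List of class `rk_truth`.
#' @export
rk_ground_truth <- function(r_max = 0.8, K_max = 1.2) {
  b_nh4_lo <- sqrt(20 * 200)     # 63.246
  b_nh4_hi <- sqrt(200 * 400)    # 282.84
  b_mg_lo <- 0.1
  b_mg_hi <- sqrt(5 * 100)       # 22.361
  b_glc <- sqrt(20 * 200)
  b_fe <- sqrt(0.1 * 10)         # 1.0
  b_thi <- sqrt(0.0015 * 0.015)  # 0.00474
  b_na <- sqrt(10 * 100)         # 31.6
  structure(list(
    r_max = r_max, K_max = K_max,
    boundaries = c(nh4_lo = b_nh4_lo, nh4_hi = b_nh4_hi, mg_lo = b_mg_lo,
                   mg_hi = b_mg_hi, glc = b_glc, fe = b_fe, thi = b_thi,
                   na = b_na),
    g_nh4 = function(c) ifelse(c > b_nh4_hi, 0,
                               ifelse(c > b_nh4_lo, 1, 0.7)),
    g_mg = function(c) ifelse(c <= b_mg_lo, 0,
                              ifelse(c <= b_mg_hi, 1, 0.75)),
    g_glc = function(c) ifelse(c <= b_glc, 1, 0.65),
    h_nh4 = function(c) ifelse(c > b_nh4_hi, 0,
                               ifelse(c > b_nh4_lo, 0.55, 1)),
    h_fe = function(c) ifelse(c <= b_fe, 1, 0.8),
    h_mg = function(c) ifelse(c <= b_mg_hi, 0.7, 1),
    h_glc = function(c) ifelse(c <= b_glc, 1, 0.65),
    h_thi = function(c) ifelse(c <= b_thi, 0.85, 1),
    h_na = function(c) ifelse(c <= b_na, 1, 0.85)),
    class = "rk_truth")
}

#' Evaluate the planted response for one media row
#'
#' @param media_row One-row [media_table()] (or a named vector of the 13
#'   component concentrations in mM).
#' @param truth An [rk_ground_truth()].
#' @return List with `r_star` (h^-1) and `K_star` (OD units).
#' @export
ground_truth_response <- function(media_row, truth = rk_ground_truth()) {
  ions <- if (inherits(media_row, "media_table"))
    drop(expand_to_ions(media_row)) else media_row
  r <- truth$r_max * truth$g_nh4(ions[["NH4"]]) *
    truth$g_mg(ions[["Mg"]]) * truth$g_glc(ions[["glucose"]])
  K <- if (r <= 0) 0 else
    truth$K_max * truth$h_nh4(ions[["NH4"]]) * truth$h_fe(ions[["Fe"]]) *
      truth$h_mg(ions[["Mg"]]) * truth$h_glc(ions[["glucose"]]) *
      truth$h_thi(ions[["thiamine"]]) * truth$h_na(ions[["Na"]])
  list(r_star = r, K_star = K)
}

#' Sample a media design from the scenario grids
#'
#' Full factorial over the varied compound grids when `n_combinations`
#' equals the number of grid cells, otherwise a seeded uniform sample of
#' cells without replacement. Fixed compounds are constant; the phosphate
#' pair is validated against the 5:3 lock.
#'
#' @param scenario An [rk_scenario()].
#' @param seed Seed for the cell sample (default `scenario$seed`).
#' @return A [media_table()] with `C = n_combinations` rows.
#' @export
sample_design <- function(scenario, seed = scenario$seed) {
  cells <- expand.grid(scenario$varied, KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  C <- scenario$n_combinations
  if (C > n_cells)
    stop("n_combinations (", C, ") exceeds the ", n_cells,
         " distinct grid cells")
  if (C < n_cells) {
    set.seed(seed)
    cells <- cells[sort(sample.int(n_cells, C)), , drop = FALSE]
  }
  df <- data.frame(combination_id = sprintf("C%03d", seq_len(C)),
                   stringsAsFactors = FALSE)
  for (cc in rk_compounds()) {
    df[[cc]] <- if (cc %in% names(cells)) cells[[cc]]
    else if (cc %in% names(scenario$fixed)) scenario$fixed[[cc]]
    else 0
  }
  media_table(df, ratio_lock = TRUE)
}

#' Simulate one raw growth curve
#'
#' Logistic growth on top of a constant optical background:
#' `OD(t) = bg + K / (1 + ((K - od0)/od0) * exp(-r (t - lag)))` for
#' r, K > 0, flat background otherwise, plus additive Gaussian read noise.
#'
#' @param r_star,K_star Planted growth rate (h^-1) and density (OD).
#' @param scenario An [rk_scenario()] (supplies times, background, od0,
#'   noise).
#' @param lag Lag time (h); default 0.
#' @param seed Optional seed for the read noise; `NULL` leaves the RNG
#'   stream alone (noise-free when `scenario$noise_sd == 0`).
#' @return List with `times` (h) and `od` (raw, pre-background-correction).
#' @export
simulate_curve <- function(r_star, K_star, scenario = rk_scenario(),
                           lag = 0, seed = NULL) {
  times <- seq(0, scenario$duration_h, by = scenario$interval_h)
  od <- scenario$background +
    logistic_od(times, r_star, K_star, scenario$od0, lag)
  if (scenario$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    od <- pmax(od + stats::rnorm(length(od), 0, scenario$noise_sd), 0)
  }
  list(times = times, od = od)
}

logistic_od <- function(times, r, K, od0, lag) {
  if (r <= 0 || K <= 0) return(rep(0, length(times)))
  K / (1 + ((K - od0) / od0) * exp(-r * (times - lag)))
}

#' Simulate a full plate dataset
#'
#' Distributes `C x N` replicate wells across 96-well plates (92 sample
#' wells plus 4 medium-only background wells each), simulates every well
#' from the planted response rules, optionally injects artifacts, and
#' emits the ground-truth table for recovery scoring. Fully
#' seed-deterministic.
#'
#' @param scenario An [rk_scenario()].
#' @param truth An [rk_ground_truth()].
#' @param artifacts Inject artifacts at the scenario rates (default TRUE).
#' @return List: `runs` (list of [plate_run()]), `layout`
#'   ([plate_layout()] with `run_id`), `media` ([media_table()]), `truth`
#'   (data frame `combination_id`, `r_star`, `K_star`: the planted
#'   combination-level response), `well_truth` (data frame `curve_id`,
#'   `combination_id`, `r_star`, `K_star`: the realized per-well response
#'   including biological variability — the reference for extraction
#'   recovery scoring), `artifact_log` (data frame `run_id`, `well_id`,
#'   `curve_id`, `type`), `scenario`.
#' @export
simulate_dataset <- function(scenario = rk_scenario(),
                             truth = rk_ground_truth(), artifacts = TRUE) {
  media <- sample_design(scenario, seed = scenario$seed)
  ions <- expand_to_ions(media)
  resp <- lapply(seq_len(nrow(ions)), function(i)
    ground_truth_response(ions[i, ], truth))
  truth_tab <- data.frame(
    combination_id = media$combination_id,
    r_star = vapply(resp, `[[`, 0, "r_star"),
    K_star = vapply(resp, `[[`, 0, "K_star"),
    stringsAsFactors = FALSE)

  C <- nrow(media); N <- scenario$replicates
  n_wells <- C * N
  per_plate <- 92L
  n_plates <- ceiling(n_wells / per_plate)
  all_pos <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  bg_pos <- c("A1", "D6", "E7", "H12")
  sample_pos <- setdiff(all_pos, bg_pos)
  times <- seq(0, scenario$duration_h, by = scenario$interval_h)

  well_combo <- rep(media$combination_id, each = N)
  set.seed(scenario$seed + 1L)
  lags <- stats::runif(n_wells, scenario$lag_range[1], scenario$lag_range[2])
  sdlog <- sqrt(log(1 + scenario$bio_cv^2))
  z1 <- stats::rnorm(n_wells)
  z2 <- scenario$bio_rho * z1 +
    sqrt(1 - scenario$bio_rho^2) * stats::rnorm(n_wells)
  bio_r <- exp(sdlog * z1 - sdlog^2 / 2)
  bio_K <- exp(sdlog * z2 - sdlog^2 / 2)
  r_by0 <- stats::setNames(truth_tab$r_star, truth_tab$combination_id)
  K_by0 <- stats::setNames(truth_tab$K_star, truth_tab$combination_id)
  well_r <- r_by0[well_combo] * bio_r
  well_K <- K_by0[well_combo] * bio_K
  well_ids <- character(n_wells)

  runs <- vector("list", n_plates)
  layout_rows <- vector("list", n_plates)
  w0 <- 0L
  for (p in seq_len(n_plates)) {
    run_id <- sprintf("P%02d", p)
    n_here <- min(per_plate, n_wells - w0)
    pos <- sample_pos[seq_len(n_here)]
    od <- matrix(0, nrow = length(times), ncol = n_here + length(bg_pos),
                 dimnames = list(NULL, c(bg_pos, pos)))
    for (b in bg_pos) od[, b] <- scenario$background
    for (i in seq_len(n_here)) {
      wi <- w0 + i
      od[, pos[i]] <- scenario$background +
        logistic_od(times, well_r[wi], well_K[wi], scenario$od0, lags[wi])
      well_ids[wi] <- paste(run_id, pos[i], sep = ".")
    }
    if (scenario$noise_sd > 0)
      od <- pmax(od + matrix(stats::rnorm(length(od), 0, scenario$noise_sd),
                             nrow = nrow(od)), 0)
    runs[[p]] <- plate_run(run_id, times, od)
    layout_rows[[p]] <- data.frame(
      run_id = run_id,
      well_id = c(bg_pos, pos),
      role = c(rep("background", length(bg_pos)), rep("sample", n_here)),
      combination_id = c(rep(NA_character_, length(bg_pos)),
                         well_combo[w0 + seq_len(n_here)]),
      stringsAsFactors = FALSE)
    w0 <- w0 + n_here
  }
  layout <- plate_layout(do.call(rbind, layout_rows))
  well_truth <- data.frame(curve_id = well_ids, combination_id = well_combo,
                           r_star = unname(well_r), K_star = unname(well_K),
                           stringsAsFactors = FALSE)

  artifact_log <- data.frame(run_id = character(), well_id = character(),
                             curve_id = character(), type = character(),
                             stringsAsFactors = FALSE)
  if (artifacts &&
      scenario$lag_spike_prob + scenario$exp_spike_prob +
        scenario$truncation_prob > 0) {
    for (p in seq_len(n_plates)) {
      inj <- inject_artifacts(runs[[p]], scenario,
                              seed = scenario$seed + 1L + p,
                              layout = layout)
      runs[[p]] <- inj$run
      artifact_log <- rbind(artifact_log, inj$log)
    }
  }
  list(runs = runs, layout = layout, media = media, truth = truth_tab,
       well_truth = well_truth, artifact_log = artifact_log,
       scenario = scenario)
}

#' Inject read artifacts into a plate run
#'
#' Per sample well, with the scenario's (mutually exclusive)
#' probabilities: a lag-phase spike (+0.1-0.3 OD at one early read), an
#' exponential-phase spike (same magnitude at one mid-rise read), or
#' truncation — the curve is shifted late so it is still rising at the end
#' of the run (the downstream incomplete signature). Every injection is
#' logged.
#'
#' @param run A [plate_run()].
#' @param scenario An [rk_scenario()] (artifact rates).
#' @param seed Seed for the injection draws.
#' @param layout Optional [plate_layout()]; restricts injection to sample
#'   wells of this run (all wells otherwise).
#' @return List: `run` (corrupted copy), `log` (data frame `run_id`,
#'   `well_id`, `curve_id`, `type`).
#' @export
inject_artifacts <- function(run, scenario, seed = scenario$seed,
                             layout = NULL) {
  wells <- colnames(run$od)
  if (!is.null(layout)) {
    lay <- layout
    if ("run_id" %in% names(lay)) lay <- lay[lay$run_id == run$run_id, ]
    wells <- intersect(wells, lay$well_id[lay$role == "sample"])
  }
  set.seed(seed)
  p1 <- scenario$lag_spike_prob
  p2 <- scenario$exp_spike_prob
  p3 <- scenario$truncation_prob
  log_rows <- list()
  od <- run$od
  n <- nrow(od)
  for (w in wells) {
    u <- stats::runif(1)
    type <- if (u < p1) "lag_spike" else if (u < p1 + p2) "exp_spike"
    else if (u < p1 + p2 + p3) "truncation" else next
    col <- od[, w]
    base <- min(col)
    amp <- max(col) - base
    if (type == "lag_spike") {
      cand <- which(col - base < 0.1 * amp)
      cand <- cand[cand > 1L & cand < n]
      if (!length(cand)) cand <- 2L
      i <- cand[sample.int(length(cand), 1L)]
      od[i, w] <- col[i] + stats::runif(1, 0.1, 0.3)
    } else if (type == "exp_spike") {
      cand <- which(col - base >= 0.2 * amp & col - base <= 0.6 * amp)
      if (!length(cand)) cand <- max(2L, floor(n / 2))
      i <- cand[sample.int(length(cand), 1L)]
      od[i, w] <- col[i] + stats::runif(1, 0.1, 0.3)
    } else {                                  # truncation: still rising
      half <- which(col - base >= 0.5 * amp)[1L]
      if (is.na(half) || amp < 0.05) next     # non-grower: nothing to cut
      shift <- n - half
      if (shift < 1L) next
      od[, w] <- c(rep(col[1L], shift), col)[seq_len(n)]
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      run_id = run$run_id, well_id = w,
      curve_id = paste(run$run_id, w, sep = "."), type = type,
      stringsAsFactors = FALSE)
  }
  run$od <- od
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(run_id = character(), well_id = character(),
               curve_id = character(), type = character(),
               stringsAsFactors = FALSE)
  list(run = run, log = log_df)
}
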