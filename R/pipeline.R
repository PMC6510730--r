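# End-to-end composition: raw plate runs -> growth records -> feature
# matrix -> rate and density trees -> mechanism calls.

#' Run the full growth-decision pipeline
#'
#' Chains background subtraction, (r, K) extraction, dataset refinement,
#' replicate aggregation, ion-feature construction, CART fitting for both
#' growth parameters, cross-validation, split stability, best/worst path
#' analysis, trade-off/uniform mechanism classification, the r-K rank
#' correlation at both data levels, and the OLS baseline. Deterministic
#' given `seed`.
#'
#' @param runs A [plate_run()] or list of them.
#' @param layout A [plate_layout()].
#' @param media A [media_table()].
#' @param depth Tree depth: an integer, or `"auto"` for
#'   [select_depth()] with `depth_grid`.
#' @param depth_grid Candidate depths for `depth = "auto"`.
#' @param k Cross-validation folds.
#' @param seed Integer seed for all randomized stages.
#' @param cfg An [extraction_config()].
#' @param level `"curve"` (one tree row per growth curve, the primary
#'   analysis) or `"combination"` (replicate means).
#' @param cv Compute k-fold CV mse for both trees.
#' @param stability_repeats Fold partitions for [split_stability()]
#'   (0 skips stability).
#' @param regression Fit the OLS baseline (collinear/constant ion columns
#'   are dropped and recorded).
#' @param min_leaf Minimum rows per tree leaf (default 20): at plate scale
#'   a leaf should represent a media class with replicate support (several
#'   combinations x replicates), as in published growth decision trees
#'   whose leaves carry dozens to hundreds of curves.
#' @param expansion Stoichiometry from [ion_expansion()].
#' @return List of class `rk_report`; see the elements in the example
#'   below. `removal_log` records refined-away curves.
#' @export
run_pipeline <- function(runs, layout, media, depth = 4L, depth_grid = 0:8,
                         k = 5L, seed = 1L, cfg = extraction_config(),
                         level = c("curve", "combination"), cv = TRUE,
                         stability_repeats = 2L, regression = TRUE,
                         min_leaf = 20L, expansion = ion_expansion()) {
  level <- match.arg(level)
  if (inherits(runs, "plate_run")) runs <- list(runs)
  if (!nrow(media)) stop("empty media table")

  curves <- unlist(lapply(runs, subtract_background, layout = layout),
                   recursive = FALSE)
  records <- extract_all(curves, cfg)
  ref <- refine_dataset(records, cfg = cfg)
  records <- ref$records
  agg <- aggregate_combinations(records)

  fm <- log_features(expand_to_ions(media, expansion), drop_all_zero = TRUE)
  if (level == "curve") {
    rows <- match(records$combination_id, rownames(fm))
    if (anyNA(rows)) stop("growth records cite combinations missing from media")
    X <- fm[rows, , drop = FALSE]
    y_r <- records$r; y_K <- records$K
  } else {
    rows <- match(agg$combination_id, rownames(fm))
    X <- fm[rows, , drop = FALSE]
    y_r <- agg$mean_r; y_K <- agg$mean_K
  }

  depth_sel <- NULL
  if (identical(depth, "auto")) {
    depth_sel <- list(r = select_depth(X, y_r, depth_grid, k = k, seed = seed,
                                       min_leaf = min_leaf),
                      K = select_depth(X, y_K, depth_grid, k = k, seed = seed,
                                       min_leaf = min_leaf))
    depth_r <- depth_sel$r$depth
    depth_K <- depth_sel$K$depth
  } else {
    depth_r <- depth_K <- as.integer(depth)
  }

  rate_tree <- fit_tree(X, y_r, max_depth = depth_r, min_leaf = min_leaf)
  density_tree <- fit_tree(X, y_K, max_depth = depth_K, min_leaf = min_leaf)

  cv_res <- if (cv)
    list(r = kfold_mse(X, y_r, depth_r, k = k, seed = seed,
                       min_leaf = min_leaf),
         K = kfold_mse(X, y_K, depth_K, k = k, seed = seed,
                       min_leaf = min_leaf)) else NULL
  stability <- if (stability_repeats > 0L)
    list(r = split_stability(X, y_r, depth_r, k = k,
                             n_repeats = stability_repeats, seed = seed,
                             min_leaf = min_leaf),
         K = split_stability(X, y_K, depth_K, k = k,
                             n_repeats = stability_repeats, seed = seed,
                             min_leaf = min_leaf))
  else NULL

  ranges <- design_ranges(media, expansion)
  paths_r <- best_worst_paths(rate_tree)
  paths_K <- best_worst_paths(density_tree)
  iv_r <- optimal_intervals(paths_r$best, ranges)
  iv_K <- optimal_intervals(paths_K$best, ranges)
  mechanism <- classify_mechanism(iv_r, iv_K)

  spearman <- list(curve = spearman_rk(records, "curve"),
                   combination = spearman_rk(records, "combination"))
  baseline <- if (regression)
    list(r = regression_baseline(X, y_r, drop_aliased = TRUE),
         K = regression_baseline(X, y_K, drop_aliased = TRUE)) else NULL

  structure(list(
    records = records, removal_log = ref$removed, aggregated = agg,
    features = fm, design_ranges = ranges,
    depth = c(r = depth_r, K = depth_K), depth_selection = depth_sel,
    rate_tree = rate_tree, density_tree = density_tree,
    cv = cv_res, stability = stability,
    paths = list(r = paths_r, K = paths_K),
    intervals = list(r = iv_r, K = iv_K),
    mechanism = mechanism, spearman = spearman, baseline = baseline,
    seed = as.integer(seed), level = level),
    class = "rk_report")
}

#' @export
print.rk_report <- function(x, ...) {
  cat("<rk_report> (level: ", x$level, ")\n", sep = "")
  cat("  curves: ", nrow(x$records), " kept, ", nrow(x$removal_log),
      " removed; combinations: ", nrow(x$aggregated), "\n", sep = "")
  cat("  tree depths: r = ", x$depth[["r"]], ", K = ", x$depth[["K"]],
      "\n", sep = "")
  if (!is.null(x$cv))
    cat("  CV mse: r = ", signif(x$cv$r$mean_mse, 3), ", K = ",
        signif(x$cv$K$mean_mse, 3), "\n", sep = "")
  root_line <- function(tree)
    if (tree$root$leaf) "single leaf (no split)"
    else paste0(tree$root$feature, " <= ", signif(tree$root$threshold, 4),
                " (log10 mM)")
  cat("  rate-tree root: ", root_line(x$rate_tree), "\n", sep = "")
  cat("  density-tree root: ", root_line(x$density_tree), "\n", sep = "")
  cat("  Spearman rho(r, K): curve = ",
      signif(x$spearman$curve$rho, 3), ", combination = ",
      signif(x$spearman$combination$rho, 3), "\n", sep = "")
  cat("  mechanism calls:\n")
  print(x$mechanism, digits = 4)
  invisible(x)
}

#' Serialize a pipeline report as JSON
#'
#' Deterministic JSON rendering of the analysis outcome (trees, CV mses,
#' stability frequencies, intervals, mechanism calls, correlations,
#' removal log). Two runs with the same inputs and seed produce identical
#' bytes.
#'
#' @param report An [run_pipeline()] result.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  x <- list(
    level = report$level, seed = report$seed,
    n_curves = nrow(report$records),
    n_removed = nrow(report$removal_log),
    removal_log = report$removal_log,
    n_combinations = nrow(report$aggregated),
    depth = as.list(report$depth),
    cv_mse = if (!is.null(report$cv))
      list(r = report$cv$r$mean_mse, K = report$cv$K$mean_mse),
    rate_tree = jsonlite::fromJSON(tree_json(report$rate_tree),
                                   simplifyVector = FALSE),
    density_tree = jsonlite::fromJSON(tree_json(report$density_tree),
                                      simplifyVector = FALSE),
    stability = if (!is.null(report$stability))
      list(r = report$stability$r$positions,
           K = report$stability$K$positions),
    intervals = report$intervals,
    mechanism = report$mechanism,
    spearman = list(curve = report$spearman$curve,
                    combination = report$spearman$combination))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
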