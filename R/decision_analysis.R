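# Biological readout of fitted trees: best/worst root-to-leaf paths,
# optimal concentration intervals per chemical, trade-off vs uniform
# mechanism calls, r-K rank correlation, and an OLS baseline.

#' Best and worst root-to-leaf paths of a tree
#'
#' The best (worst) path is the root-to-leaf path reaching the maximal
#' (minimal) leaf mean target; ties are resolved toward the larger leaf
#' `n`, then the leftmost leaf.
#'
#' @param tree An [fit_tree()] result.
#' @return List with elements `best` and `worst`, each a `leaf_path`: a
#'   list with `constraints` (data frame: `component`, `direction`
#'   (`"<="`/`">"`), `threshold_log10`, `threshold_mM`), `leaf_mean`,
#'   `leaf_n`. A depth-0 tree yields empty constraint lists.
#' @export
best_worst_paths <- function(tree) {
  leaves <- list()
  walk <- function(node, constraints) {
    if (node$leaf) {
      leaves[[length(leaves) + 1L]] <<-
        list(constraints = constraints, mean = node$mean, n = node$n)
      return(invisible())
    }
    row <- function(dir) data.frame(
      component = node$feature, direction = dir,
      threshold_log10 = node$threshold,
      threshold_mM = 10^node$threshold, stringsAsFactors = FALSE)
    walk(node$left, rbind(constraints, row("<=")))
    walk(node$right, rbind(constraints, row(">")))
  }
  empty <- data.frame(component = character(), direction = character(),
                      threshold_log10 = numeric(), threshold_mM = numeric(),
                      stringsAsFactors = FALSE)
  walk(tree$root, empty)
  means <- vapply(leaves, `[[`, 0, "mean")
  ns <- vapply(leaves, `[[`, 0, "n")
  pick <- function(target) {
    cand <- which(means == target)
    cand[which.max(ns[cand])]          # ties: larger n, then leftmost
  }
  as_path <- function(leaf)
    structure(list(constraints = leaf$constraints, leaf_mean = leaf$mean,
                   leaf_n = leaf$n), class = "leaf_path")
  list(best = as_path(leaves[[pick(max(means))]]),
       worst = as_path(leaves[[pick(min(means))]]))
}

#' @export
print.leaf_path <- function(x, ...) {
  cat("<leaf_path> mean = ", signif(x$leaf_mean, 4), ", n = ", x$leaf_n,
      "\n", sep = "")
  if (nrow(x$constraints)) {
    with(x$constraints,
         cat(paste0("  ", component, " ", direction, " ",
                    signif(threshold_mM, 4), " mM (",
                    signif(threshold_log10, 4), " log10)\n"), sep = ""))
  } else cat("  (no constraints: single leaf)\n")
  invisible(x)
}

#' Optimal concentration intervals along a path
#'
#' Intersects all path constraints per component into one concentration
#' interval (mM); the unconstrained side is filled from the design's
#' tested range. Thresholds are back-transformed with `10^x`.
#'
#' @param path A `leaf_path` from [best_worst_paths()].
#' @param design_ranges Data frame `component`, `min_mM`, `max_mM`: the
#'   tested concentration range per component (see [design_ranges()]).
#' @param components Components to report; default those constrained by
#'   the path. Components absent from the path get their full design
#'   range.
#' @return Data frame: `component`, `lower_mM`, `upper_mM`,
#'   `lower_bounded`, `upper_bounded` (whether the bound comes from the
#'   path rather than the design).
#' @export
optimal_intervals <- function(path, design_ranges, components = NULL) {
  cons <- path$constraints
  if (is.null(components)) components <- unique(cons$component)
  out <- lapply(components, function(cmp) {
    dr <- design_ranges[design_ranges$component == cmp, , drop = FALSE]
    if (!nrow(dr)) stop("no design range for component ", cmp)
    cc <- cons[cons$component == cmp, , drop = FALSE]
    lowers <- cc$threshold_mM[cc$direction == ">"]
    uppers <- cc$threshold_mM[cc$direction == "<="]
    lower <- if (length(lowers)) max(lowers) else dr$min_mM
    upper <- if (length(uppers)) min(uppers) else dr$max_mM
    if (lower >= upper)
      stop("contradictory constraints for ", cmp, ": (",
           signif(lower, 4), ", ", signif(upper, 4), ")")
    data.frame(component = cmp, lower_mM = lower, upper_mM = upper,
               lower_bounded = length(lowers) > 0L,
               upper_bounded = length(uppers) > 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tested concentration ranges of the components
#'
#' Min/max component concentration over the combinations of a media table
#' (on the ion scale); stands in for the unbounded side of an optimal
#' interval.
#'
#' @param media A [media_table()].
#' @param expansion Stoichiometry from [ion_expansion()].
#' @return Data frame: `component`, `min_mM`, `max_mM`.
#' @export
design_ranges <- function(media, expansion = ion_expansion()) {
  comp <- expand_to_ions(media, expansion)
  data.frame(component = colnames(comp),
             min_mM = apply(comp, 2, min),
             max_mM = apply(comp, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify decision chemicals as trade-off vs uniform
#'
#' Compares, per component, the optimal concentration interval for fast
#' growth (rate tree best path) with the one for high density (density
#' tree best path). Overlapping interval interiors mean the chemical works
#' uniformly for both objectives; disjoint interiors (including intervals
#' touching only at an endpoint) mean a trade-off. Components constrained
#' in only one of the two paths are `unshared`.
#'
#' @param rate_intervals,density_intervals Data frames from
#'   [optimal_intervals()] for the rate and density best paths.
#' @return Data frame: `component`, `rate_lower`, `rate_upper`,
#'   `density_lower`, `density_upper` (mM; `NA` for unshared sides),
#'   `call` (`uniform` / `trade_off` / `unshared`).
#' @export
classify_mechanism <- function(rate_intervals, density_intervals) {
  comps <- union(rate_intervals$component, density_intervals$component)
  if (!length(comps))
    return(data.frame(component = character(), rate_lower = numeric(),
                      rate_upper = numeric(), density_lower = numeric(),
                      density_upper = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  out <- lapply(comps, function(cmp) {
    ri <- rate_intervals[rate_intervals$component == cmp, , drop = FALSE]
    di <- density_intervals[density_intervals$component == cmp, , drop = FALSE]
    if (!nrow(ri) || !nrow(di)) {
      call <- "unshared"
      lw <- function(x) if (nrow(x)) x$lower_mM else NA_real_
      up <- function(x) if (nrow(x)) x$upper_mM else NA_real_
      return(data.frame(component = cmp, rate_lower = lw(ri),
                        rate_upper = up(ri), density_lower = lw(di),
                        density_upper = up(di), call = call,
                        stringsAsFactors = FALSE))
    }
    overlap <- max(ri$lower_mM, di$lower_mM) < min(ri$upper_mM, di$upper_mM)
    data.frame(component = cmp, rate_lower = ri$lower_mM,
               rate_upper = ri$upper_mM, density_lower = di$lower_mM,
               density_upper = di$upper_mM,
               call = if (overlap) "uniform" else "trade_off",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation between r and K
#'
#' Rank correlation (average ranks for ties) between growth rate and
#' saturated density, at the individual-curve or the per-combination
#' (replicate-mean) level; p-value from the t approximation on n - 2
#' degrees of freedom.
#'
#' @param records A [growth_records()] table.
#' @param level `"curve"` (one point per growth curve) or `"combination"`
#'   (one point per combination mean).
#' @return List: `rho`, `p`, `n`, `level`. `rho` is `NA` (with `p` `NA`)
#'   when either variable is constant.
#' @export
spearman_rk <- function(records, level = c("curve", "combination")) {
  level <- match.arg(level)
  if (level == "combination") {
    agg <- aggregate_combinations(records, n_min = 1L)
    x <- agg$mean_r; y <- agg$mean_K
  } else {
    x <- records$r; y <- records$K
  }
  n <- length(x)
  if (n < 3L) stop("need >= 3 rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, level = level))
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, level = level)
}

#' Multivariate OLS baseline
#'
#' Ordinary least squares of the growth parameter on the 13 component
#' features plus an intercept, the conventional analysis the tree
#' learning is contrasted with. Perfectly collinear or constant columns
#' make the design rank-deficient; by default this is an error naming the
#' offending columns (drop one of each confounded pair, or set
#' `drop_aliased = TRUE`).
#'
#' @param X Feature matrix from [log_features()].
#' @param y Numeric target.
#' @param drop_aliased Drop constant/aliased columns (recorded in the
#'   result) instead of failing.
#' @return List of class `rk_regression`: `coefficients` (data frame:
#'   `component`, `estimate`, `std_error`, `t`, `p`, `significant` at
#'   0.05), `dropped` (character), `r_squared`.
#' @export
regression_baseline <- function(X, y, drop_aliased = FALSE) {
  X <- as.matrix(X)
  if (length(y) <= ncol(X) + 1L)
    stop("need n > number of features + 1")
  dropped <- character()
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    if (!drop_aliased)
      stop("constant feature column(s): ",
           paste(colnames(X)[const], collapse = ", "))
    dropped <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
  }
  df <- as.data.frame(X)
  fit <- stats::lm(y ~ ., data = df)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    aliased <- gsub("`", "", aliased)
    if (!drop_aliased)
      stop("rank-deficient design; collinear column(s): ",
           paste(aliased, collapse = ", "))
    dropped <- c(dropped, aliased)
    df <- df[, setdiff(names(df), aliased), drop = FALSE]
    fit <- stats::lm(y ~ ., data = df)
  }
  sm <- summary(fit)
  tab <- stats::coef(sm)
  comp <- gsub("`", "", rownames(tab))
  coefs <- data.frame(component = comp, estimate = tab[, 1],
                      std_error = tab[, 2], t = tab[, 3], p = tab[, 4],
                      significant = tab[, 4] < 0.05,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, dropped = dropped,
                 r_squared = sm$r.squared),
            class = "rk_regression")
}

#' @export
print.rk_regression <- function(x, ...) {
  cat("<rk_regression> R^2 = ", signif(x$r_squared, 3), sep = "")
  if (length(x$dropped))
    cat("; dropped: ", paste(x$dropped, collapse = ", "), sep = "")
  cat("\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
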