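# CART regression trees from scratch: greedy binary recursive partitioning
# minimizing within-child squared error, midpoint thresholds, deterministic
# tie-breaking; k-fold CV, mse-plateau depth selection, split stability.

#' Fit a CART regression tree
#'
#' Greedy recursive partitioning. At each node every feature is scanned;
#' candidate thresholds are arithmetic midpoints between consecutive sorted
#' distinct values, and the split minimizing the summed within-child
#' squared error (maximal variance reduction) is taken. Rows with
#' `feature <= threshold` go left. Splitting stops at `max_depth`, when a
#' node has fewer than `2 * min_leaf` rows, or when no split reduces the
#' error. Ties are broken deterministically: lower feature column index,
#' then lower threshold.
#'
#' On log10-concentration features, midpoint thresholds back-transform to
#' geometric means of adjacent tested concentrations (e.g. levels 20 and
#' 200 mM give a boundary at 63.2 mM).
#'
#' @param X Numeric matrix or data frame of features (no missing values).
#' @param y Numeric target (growth rate in h^-1 or saturated density in OD
#'   units), `length(y) == nrow(X)`.
#' @param max_depth Maximum tree depth (0 = single leaf).
#' @param min_leaf Minimum rows per leaf (default 5).
#' @return An object of class `rk_tree`.
#' @export
fit_tree <- function(X, y, max_depth = 4L, min_leaf = 5L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!nrow(X) || !length(y)) stop("empty data")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  max_depth <- as.integer(max_depth); min_leaf <- as.integer(min_leaf)

  grow <- function(idx, depth) {
    yy <- y[idx]
    n <- length(idx)
    mu <- mean(yy)
    sse <- sum((yy - mu)^2)
    node <- list(n = n, mean = mu, mse = sse / n, depth = depth)
    if (depth >= max_depth || n < 2L * min_leaf || sse <= 0) {
      node$leaf <- TRUE
      return(node)
    }
    sp <- best_split(X[idx, , drop = FALSE], yy, min_leaf)
    if (is.null(sp) || sp$cost >= sse * (1 - 1e-12)) {
      node$leaf <- TRUE
      return(node)
    }
    go_left <- X[idx, sp$j] <= sp$threshold
    node$leaf <- FALSE
    node$j <- sp$j
    node$feature <- colnames(X)[sp$j]
    node$threshold <- sp$threshold
    node$left <- grow(idx[go_left], depth + 1L)
    node$right <- grow(idx[!go_left], depth + 1L)
    node
  }

  structure(list(root = grow(seq_along(y), 0L), features = colnames(X),
                 max_depth = max_depth, min_leaf = min_leaf,
                 n = length(y)),
            class = "rk_tree")
}

# scan all features for the minimum-cost split; cost = summed child SSE
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cy <- cumsum(ys); cy2 <- cumsum(ys * ys)
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(ok)) next
    i <- i[ok]
    left <- cy2[i] - cy[i]^2 / i
    right <- (cy2[n] - cy2[i]) - (cy[n] - cy[i])^2 / (n - i)
    cost <- pmax(left, 0) + pmax(right, 0)
    b <- which.min(cost)                     # first minimum: lowest threshold
    # strict improvement keeps the earlier (lower-index) feature on ties
    if (is.null(best) ||
        cost[b] < best$cost - 1e-12 * max(1, abs(best$cost))) {
      best <- list(j = j, threshold = (xs[i[b]] + xs[i[b] + 1L]) / 2,
                   cost = cost[b])
    }
  }
  best
}

#' Predict from a CART regression tree
#'
#' Routes each row by threshold comparisons (`<=` goes left) and returns
#' the leaf mean target.
#'
#' @param object An [fit_tree()] result.
#' @param newdata Matrix or data frame containing the training feature
#'   columns (by name).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rk_tree <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in feature columns")
  route <- function(node, rows) {
    if (node$leaf) {
      out[rows] <<- node$mean
      return(invisible())
    }
    lhs <- X[rows, node$j] <= node$threshold
    if (any(lhs)) route(node$left, rows[lhs])
    if (any(!lhs)) route(node$right, rows[!lhs])
  }
  out <- numeric(nrow(X))
  if (nrow(X)) route(object$root, seq_len(nrow(X)))
  out
}

#' @export
print.rk_tree <- function(x, ...) {
  cat("<rk_tree> n = ", x$n, ", max_depth = ", x$max_depth, "\n", sep = "")
  show <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, label, " leaf: n = ", node$n, ", mean = ",
          signif(node$mean, 4), "\n", sep = "")
    } else {
      cat(pad, label, " ", node$feature, " <= ", signif(node$threshold, 4),
          " | n = ", node$n, ", mean = ", signif(node$mean, 4),
          ", mse = ", signif(node$mse, 3), "\n", sep = "")
      show(node$left, indent + 1L, "L")
      show(node$right, indent + 1L, "R")
    }
  }
  show(x$root, 0L, "root")
  invisible(x)
}

#' Serialize a tree as nested JSON
#'
#' Per node: feature, threshold, n, mean, mse, children — the per-node
#' quadruple of the tree figures plus the node mse.
#'
#' @param tree An [fit_tree()] result.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_json <- function(tree, path = NULL) {
  as_list <- function(node) {
    if (node$leaf)
      list(n = node$n, mean = node$mean, mse = node$mse)
    else
      list(feature = node$feature, threshold = node$threshold,
           n = node$n, mean = node$mean, mse = node$mse,
           left = as_list(node$left), right = as_list(node$right))
  }
  js <- jsonlite::toJSON(as_list(tree$root), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# seed-deterministic fold assignment: near-equal random folds
make_folds <- function(n, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of rows")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' k-fold cross-validated mean squared error
#'
#' Random partition into k near-equal folds under the given seed; for each
#' fold a tree is fitted on the remaining folds and scored on the held-out
#' fold.
#'
#' @inheritParams fit_tree
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List of class `cv_result`: `k`, `fold_mse`, `mean_mse`, `seed`.
#' @export
kfold_mse <- function(X, y, max_depth = 4L, k = 5L, seed = 1L,
                      min_leaf = 5L) {
  X <- as.matrix(X)
  n <- length(y)
  folds <- make_folds(n, k, seed)
  fold_mse <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- fit_tree(X[tr, , drop = FALSE], y[tr], max_depth, min_leaf)
    mean((predict(fit, X[!tr, , drop = FALSE]) - y[!tr])^2)
  }, 0)
  structure(list(k = as.integer(k), fold_mse = fold_mse,
                 mean_mse = mean(fold_mse), seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> k = ", x$k, ", mean mse = ", signif(x$mean_mse, 4),
      "\n", sep = "")
  invisible(x)
}

#' Select tree depth by the CV mse plateau
#'
#' Computes the k-fold CV mse for each depth in `depth_grid` (same folds at
#' every depth) and returns the smallest depth at which moving to the next
#' grid depth changes the mean mse by at most `tol` (absolute, on the
#' squared target scale). If the mse never plateaus, the depth of minimal
#' mean mse is returned.
#'
#' @inheritParams kfold_mse
#' @param depth_grid Increasing integer vector of candidate depths.
#' @param tol Absolute plateau tolerance on the mean mse (default 0.001).
#' @return List: `depth` (selected), `grid`, `mean_mse` (per grid depth).
#' @export
select_depth <- function(X, y, depth_grid = 0:8, tol = 0.001, k = 5L,
                         seed = 1L, min_leaf = 5L) {
  if (is.unsorted(depth_grid, strictly = TRUE))
    stop("depth_grid must be strictly increasing")
  mses <- vapply(depth_grid, function(d)
    kfold_mse(X, y, max_depth = d, k = k, seed = seed,
              min_leaf = min_leaf)$mean_mse, 0)
  depth <- NA_integer_
  if (length(depth_grid) > 1L) {
    for (i in seq_len(length(depth_grid) - 1L)) {
      if (abs(mses[i + 1L] - mses[i]) <= tol) {
        depth <- depth_grid[i]
        break
      }
    }
  }
  if (is.na(depth)) depth <- depth_grid[which.min(mses)]
  list(depth = as.integer(depth), grid = depth_grid, mean_mse = mses)
}

#' Split-variable stability across resampled training sets
#'
#' Over `n_repeats` random k-fold partitions, a tree is fitted on each of
#' the `k * n_repeats` training sets (each leaving one fold out) and the
#' split feature occupying every node position is recorded. The per-position
#' frequency of each feature measures how stable the tree's choices are;
#' confounded (highly correlated) features alternate at the same position.
#'
#' @inheritParams kfold_mse
#' @param n_repeats Number of independent fold partitions (default 1).
#' @return List of class `stability_report`: `positions` (named list,
#'   position -> named frequency vector over features, denominators
#'   `k * n_repeats` so frequencies at a position sum to <= 1), `n_fits`.
#'   Positions are `"root"`, `"root.L"`, `"root.R"`, `"root.L.L"`, ...
#' @export
split_stability <- function(X, y, max_depth = 4L, k = 5L, n_repeats = 1L,
                            seed = 1L, min_leaf = 5L) {
  X <- as.matrix(X)
  n <- length(y)
  counts <- list()
  note <- function(node, pos) {
    if (node$leaf) return(invisible())
    tab <- counts[[pos]]
    if (is.null(tab)) tab <- integer()
    tab[node$feature] <- (if (is.na(tab[node$feature])) 0L
                          else tab[node$feature]) + 1L
    counts[[pos]] <<- tab
    note(node$left, paste0(pos, ".L"))
    note(node$right, paste0(pos, ".R"))
  }
  n_fits <- 0L
  for (rep_i in seq_len(n_repeats)) {
    folds <- make_folds(n, k, seed + rep_i - 1L)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_tree(X[tr, , drop = FALSE], y[tr], max_depth, min_leaf)
      note(fit$root, "root")
      n_fits <- n_fits + 1L
    }
  }
  positions <- lapply(counts, function(tab) tab / n_fits)
  structure(list(positions = positions, n_fits = n_fits),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> ", x$n_fits, " fits\n", sep = "")
  for (pos in names(x$positions)) {
    fr <- sort(x$positions[[pos]], decreasing = TRUE)
    cat("  ", pos, ": ",
        paste(names(fr), signif(fr, 3), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
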