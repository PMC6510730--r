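# ---- compound vocabulary ----------------------------------------------------

#' The ten media compounds of the growth assay
#'
#' Fixed compound vocabulary: the essential and accessory compounds whose
#' concentrations (mM) define one media combination. Column order of every
#' [media_table()].
#'
#' @return Character vector of length 10.
#' @export
rk_compounds <- function() {
  c("glucose", "(NH4)2SO4", "K2HPO4", "KH2PO4", "MgSO4",
    "thiamine_HCl", "FeSO4", "NaCl", "leucine", "histidine")
}

# ---- PlateRun ---------------------------------------------------------------

#' Construct a validated plate run
#'
#' A plate run is one kinetic read of a microplate: a strictly increasing
#' time base (hours) and one OD600 series per well.
#'
#' @param run_id Identifier for the run (plate).
#' @param times Numeric vector of timepoints in hours, strictly increasing.
#' @param od Numeric matrix, `length(times)` rows, one named column per well.
#'   Trailing `NA`s in a column are permitted only when `allow_trailing_na`
#'   is set (a well whose export stopped early); internal gaps are rejected.
#' @param allow_trailing_na Tolerate trailing missing readings in a well.
#' @return An object of class `plate_run`.
#' @export
plate_run <- function(run_id, times, od, allow_trailing_na = FALSE) {
  times <- as.numeric(times)
  od <- as.matrix(od)
  if (is.null(colnames(od)) || anyDuplicated(colnames(od)))
    stop("'od' must have unique well-ID column names")
  if (nrow(od) != length(times))
    stop("every well needs exactly length(times) readings")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing (>= 2 timepoints)")
  for (w in colnames(od)) {
    col <- od[, w]
    miss <- is.na(col)
    if (any(miss)) {
      if (!allow_trailing_na)
        stop("missing readings in well ", w,
             " (set allow_trailing_na/tolerate_missing to truncate a trailing gap)")
      first_na <- which(miss)[1L]
      if (!all(miss[first_na:length(col)]))
        stop("internal gap in well ", w, ": only trailing gaps can be truncated")
      if (first_na <= 2L)
        stop("well ", w, " has fewer than 2 readings")
    }
    if (any(!is.finite(col[!miss])) || any(col[!miss] < 0))
      stop("non-finite or negative OD600 readings in well ", w)
  }
  structure(list(run_id = as.character(run_id), times = times, od = od),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  cat("<plate_run> ", x$run_id, ": ", ncol(x$od), " wells x ",
      length(x$times), " reads, t = ", min(x$times), "..", max(x$times),
      " h\n", sep = "")
  invisible(x)
}

#' Read a plate-reader kinetic export
#'
#' Reads a wide table whose first column is time and whose remaining columns
#' are wells, keyed by header (column order is irrelevant). Comma- and
#' tab-separated files are accepted; the separator is sniffed from the header
#' line unless given.
#'
#' @param path File path.
#' @param time_unit `"h"` (default) or `"min"`; minute input is divided by 60.
#' @param sep Field separator; `NULL` to sniff `","` vs `"\t"`.
#' @param run_id Run identifier; defaults to the file name without extension.
#' @param tolerate_missing Truncate a well's trailing gap of missing cells
#'   instead of failing. Internal gaps always fail.
#' @return A [plate_run()].
#' @export
read_plate_run <- function(path, time_unit = c("h", "min"), sep = NULL,
                           run_id = NULL, tolerate_missing = FALSE) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected a time column plus at least one well")
  times <- as.numeric(tab[[1L]])
  if (anyNA(times)) stop("non-numeric values in the time column")
  if (time_unit == "min") times <- times / 60
  od <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(od) <- "double"
  if (is.null(run_id))
    run_id <- sub("\\.[^.]*$", "", basename(path))
  plate_run(run_id, times, od, allow_trailing_na = tolerate_missing)
}

#' Write a plate run as CSV
#'
#' @param run A [plate_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate_run <- function(run, path) {
  stopifnot(inherits(run, "plate_run"))
  tab <- data.frame(time_h = run$times, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(run$od, check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

# ---- PlateLayout ------------------------------------------------------------

#' Construct a validated plate layout
#'
#' Maps wells to roles (`sample`, `background`, `empty`) and sample wells to
#' their media-combination IDs. Well IDs are opaque strings; a `run_id`
#' column links wells to runs in multi-plate datasets.
#'
#' @param df Data frame with columns `well_id`, `role`, `combination_id`
#'   (and optionally `run_id`).
#' @return An object of class `plate_layout` (a data frame).
#' @export
plate_layout <- function(df) {
  need <- c("well_id", "role", "combination_id")
  if (!all(need %in% names(df)))
    stop("layout needs columns: ", paste(need, collapse = ", "))
  df$well_id <- as.character(df$well_id)
  df$role <- as.character(df$role)
  df$combination_id <- as.character(df$combination_id)
  df$combination_id[df$combination_id %in% c("", "NA")] <- NA_character_
  key <- if ("run_id" %in% names(df)) paste(df$run_id, df$well_id) else df$well_id
  if (anyDuplicated(key)) stop("duplicate well_id rows in layout")
  if (!all(df$role %in% c("sample", "background", "empty")))
    stop("role must be one of sample/background/empty")
  if (!any(df$role == "background"))
    stop("layout has no background (medium-only) wells")
  bad <- df$role == "sample" & is.na(df$combination_id)
  if (any(bad))
    stop("sample wells without combination_id: ",
         paste(utils::head(df$well_id[bad], 5L), collapse = ", "))
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Read a plate layout table
#'
#' @inheritParams read_plate_run
#' @return A [plate_layout()].
#' @export
read_layout <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  plate_layout(df)
}

#' Write a plate layout as CSV
#' @param layout A [plate_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

# ---- MediaTable -------------------------------------------------------------

#' Construct a validated media composition table
#'
#' One row per media combination, one column per compound of
#' [rk_compounds()], concentrations in mM.
#'
#' @param df Data frame with column `combination_id` plus the ten compounds.
#' @param allow_extra Keep (ignore) unknown compound columns instead of
#'   failing.
#' @param ratio_lock Enforce a fixed K2HPO4/KH2PO4 ratio (the buffering
#'   constraint) across all combinations.
#' @param phosphate_ratio The locked ratio, default 5/3 (the 5:3 stock).
#' @return An object of class `media_table` (a data frame).
#' @export
media_table <- function(df, allow_extra = FALSE, ratio_lock = FALSE,
                        phosphate_ratio = 5 / 3) {
  if (!"combination_id" %in% names(df))
    stop("media table needs a combination_id column")
  df$combination_id <- as.character(df$combination_id)
  if (anyDuplicated(df$combination_id)) stop("duplicate combination_id")
  comp <- rk_compounds()
  missing <- setdiff(comp, names(df))
  if (length(missing))
    stop("missing compound columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c("combination_id", comp))
  if (length(extra) && !allow_extra)
    stop("unknown compound columns: ", paste(extra, collapse = ", "),
         " (set allow_extra = TRUE to ignore)")
  df <- df[, c("combination_id", comp)]
  for (cc in comp) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (anyNA(df[[cc]]) || any(df[[cc]] < 0))
      stop("negative or missing concentration in ", cc)
  }
  if (ratio_lock) {
    num <- df[["K2HPO4"]]; den <- df[["KH2PO4"]]
    both <- num > 0 | den > 0
    ok <- abs(num[both] - phosphate_ratio * den[both]) <=
      1e-8 * pmax(1, num[both])
    if (!all(ok))
      stop("K2HPO4/KH2PO4 ratio differs from the locked ",
           signif(phosphate_ratio, 4), " in ", sum(!ok), " combination(s)")
  }
  structure(df, class = c("media_table", "data.frame"),
            ratio_lock = ratio_lock)
}

#' Read a media composition table
#'
#' @inheritParams media_table
#' @inheritParams read_plate_run
#' @return A [media_table()].
#' @export
read_media_table <- function(path, sep = NULL, allow_extra = FALSE,
                             ratio_lock = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  media_table(df, allow_extra = allow_extra, ratio_lock = ratio_lock)
}

#' Write a media table as CSV
#' @param media A [media_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_media_table <- function(media, path) {
  utils::write.csv(as.data.frame(media), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- GrowthRecordTable ------------------------------------------------------

growth_record_columns <- function() {
  c("curve_id", "combination_id", "replicate_index", "r", "K", "qc_flags")
}

#' Validate a growth-record table
#'
#' One row per growth curve: `curve_id`, `combination_id`,
#' `replicate_index`, `r` (h^-1), `K` (OD units) and a `qc_flags` string
#' (flags separated by `;`, empty when clean).
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame, class `growth_records`.
#' @export
growth_records <- function(df) {
  need <- growth_record_columns()
  if (!all(need %in% names(df)))
    stop("growth table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$curve_id <- as.character(df$curve_id)
  df$combination_id <- as.character(df$combination_id)
  df$replicate_index <- as.integer(df$replicate_index)
  df$r <- as.numeric(df$r)
  df$K <- as.numeric(df$K)
  df$qc_flags <- as.character(df$qc_flags)
  df$qc_flags[is.na(df$qc_flags)] <- ""
  if (nrow(df)) {
    if (any(!is.finite(df$r)) || any(df$r < 0)) stop("r must be finite and >= 0")
    if (any(!is.finite(df$K)) || any(df$K < 0)) stop("K must be finite and >= 0")
    if (anyDuplicated(paste(df$combination_id, df$replicate_index)))
      stop("(combination_id, replicate_index) must be unique")
  }
  class(df) <- c("growth_records", "data.frame")
  df
}

#' Write a growth-record table as CSV
#'
#' Fixed column order and header; numeric values at 6 significant digits so
#' the file round-trips through [read_growth_table()] value-identically.
#'
#' @param table A [growth_records()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(table, path) {
  table <- growth_records(table)
  out <- as.data.frame(table)
  out$r <- signif(out$r, 6)
  out$K <- signif(out$K, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a growth-record table written by [write_growth_table()]
#' @inheritParams read_plate_run
#' @return A [growth_records()] table.
#' @export
read_growth_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  growth_records(df)
}

# ---- validation report ------------------------------------------------------

#' Cross-validate a run, layout and media table
#'
#' Report-only consistency check: orphan wells (in the run but not the
#' layout, or vice versa), sample wells citing unknown combinations, and
#' replicate counts per combination with a low-replicate warning.
#'
#' @param run A [plate_run()] or list of them.
#' @param layout A [plate_layout()].
#' @param media A [media_table()].
#' @param n_min Minimum replicate count before a low-replicate issue is
#'   reported (default 3).
#' @return A list of class `rk_validation` with elements `issues`
#'   (data frame: severity, code, detail) and `replicates` (data frame:
#'   combination_id, n_wells).
#' @export
validate_dataset <- function(run, layout, media, n_min = 3L) {
  runs <- if (inherits(run, "plate_run")) list(run) else run
  issues <- list()
  add <- function(severity, code, detail)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, detail = detail,
      stringsAsFactors = FALSE)

  lay_key <- layout_keys(layout)
  run_key <- unlist(lapply(runs, function(rn)
    paste(rn$run_id, colnames(rn$od))), use.names = FALSE)
  if ("run_id" %in% names(layout)) {
    orphan_run <- setdiff(run_key, lay_key)
    orphan_lay <- setdiff(lay_key, run_key)
  } else {
    wells <- unlist(lapply(runs, function(rn) colnames(rn$od)))
    orphan_run <- setdiff(wells, layout$well_id)
    orphan_lay <- setdiff(layout$well_id, wells)
  }
  for (w in orphan_run) add("warning", "well_not_in_layout", w)
  for (w in orphan_lay) add("warning", "well_not_in_run", w)

  samp <- layout[layout$role == "sample", , drop = FALSE]
  unknown <- setdiff(samp$combination_id, media$combination_id)
  for (u in unknown) add("error", "unknown_combination", u)
  absent <- setdiff(media$combination_id, samp$combination_id)
  for (a in absent) add("warning", "combination_without_wells", a)

  reps <- as.data.frame(table(samp$combination_id), stringsAsFactors = FALSE)
  names(reps) <- c("combination_id", "n_wells")
  low <- reps$combination_id[reps$n_wells < n_min]
  for (l in low)
    add("warning", "low_replicates",
        paste0(l, " (n=", reps$n_wells[reps$combination_id == l], ")"))

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), code = character(),
               detail = character(), stringsAsFactors = FALSE)
  structure(list(issues = issues, replicates = reps),
            class = "rk_validation")
}

layout_keys <- function(layout) {
  if ("run_id" %in% names(layout))
    paste(layout$run_id, layout$well_id)
  else layout$well_id
}

#' @export
print.rk_validation <- function(x, ...) {
  cat("<rk_validation> ", nrow(x$issues), " issue(s), ",
      nrow(x$replicates), " combination(s)\n", sep = "")
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}
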