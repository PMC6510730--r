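# Stoichiometric expansion of compound recipes into ionic/molecular
# components and the log10 feature matrix used for tree learning.

#' The 13 ionic/molecular components
#'
#' Fixed component vocabulary (and feature-matrix column order) obtained by
#' dissolving the ten compounds. Primary nutrient ions/molecules come
#' first; the counter-ions that are sums over several compounds (SO4, Cl,
#' H) come last, so that the deterministic tie-breaking of tree learning
#' (lower column index wins an exactly tied split) attributes a split to
#' the primary ion rather than to a composite counter-ion that happens to
#' separate the same combinations.
#'
#' @return Character vector of length 13.
#' @export
rk_components <- function() {
  c("glucose", "NH4", "K", "PO4", "Mg", "thiamine", "Fe", "Na",
    "leucine", "histidine", "SO4", "Cl", "H")
}

#' Canonical compound-to-component stoichiometry
#'
#' Integer coefficient matrix mapping each compound of [rk_compounds()] to
#' the components of [rk_components()]: e.g. one (NH4)2SO4 yields two NH4
#' and one SO4; thiamine hydrochloride yields thiamine, H and Cl. Hydrate
#' water contributes nothing.
#'
#' @param so4_from_nh4_only Drop the sulfate contributions of MgSO4 and
#'   FeSO4, as in a design where magnesium and iron are supplied as
#'   non-sulfate salts; sulfate then tracks ammonium sulfate exactly
#'   (useful for studying confounded-ion behaviour).
#' @return 10 x 13 numeric matrix (compounds x components).
#' @export
ion_expansion <- function(so4_from_nh4_only = FALSE) {
  comp <- rk_compounds(); ions <- rk_components()
  M <- matrix(0, nrow = length(comp), ncol = length(ions),
              dimnames = list(comp, ions))
  M["glucose", "glucose"] <- 1
  M["(NH4)2SO4", c("NH4", "SO4")] <- c(2, 1)
  M["K2HPO4", c("K", "PO4")] <- c(2, 1)
  M["KH2PO4", c("K", "PO4")] <- c(1, 1)
  M["MgSO4", c("Mg", "SO4")] <- c(1, 1)
  M["thiamine_HCl", c("thiamine", "H", "Cl")] <- c(1, 1, 1)
  M["FeSO4", c("Fe", "SO4")] <- c(1, 1)
  M["NaCl", c("Na", "Cl")] <- c(1, 1)
  M["leucine", "leucine"] <- 1
  M["histidine", "histidine"] <- 1
  if (so4_from_nh4_only) M[c("MgSO4", "FeSO4"), "SO4"] <- 0
  M
}

#' Expand a media table to component concentrations
#'
#' Component concentration = sum over compounds of stoichiometric
#' coefficient times compound concentration (mM).
#'
#' @param media A [media_table()].
#' @param expansion Stoichiometry matrix from [ion_expansion()].
#' @return Numeric matrix, combinations x 13 components, rownames =
#'   combination IDs.
#' @export
expand_to_ions <- function(media, expansion = ion_expansion()) {
  comp <- rk_compounds()
  if (!all(comp %in% rownames(expansion)))
    stop("expansion must cover all compounds of rk_compounds()")
  conc <- as.matrix(as.data.frame(media)[, comp])
  storage.mode(conc) <- "double"
  out <- conc %*% expansion[comp, , drop = FALSE]
  rownames(out) <- media$combination_id
  out
}

#' Log10-transform component concentrations into the feature matrix
#'
#' Concentrations are log10-transformed (log10 mM). Zeros are floored at
#' one decade below the smallest positive value of that column (the
#' recorded `zero_floor`), keeping the matrix finite.
#'
#' @param components Matrix from [expand_to_ions()] (mM, values >= 0).
#' @param drop_all_zero Drop columns that are zero everywhere instead of
#'   failing.
#' @return Numeric matrix of log10 concentrations with attribute
#'   `zero_floor` (named numeric: substituted log value per column that
#'   contained zeros).
#' @export
log_features <- function(components, drop_all_zero = FALSE) {
  X <- as.matrix(components)
  if (any(X < 0)) stop("component concentrations must be >= 0")
  all_zero <- colSums(X > 0) == 0L
  if (any(all_zero)) {
    if (!drop_all_zero)
      stop("all-zero component column(s): ",
           paste(colnames(X)[all_zero], collapse = ", "),
           " (uninformative; set drop_all_zero = TRUE to drop)")
    X <- X[, !all_zero, drop = FALSE]
  }
  floors <- numeric()
  out <- X
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    z <- x == 0
    out[!z, j] <- log10(x[!z])
    if (any(z)) {
      fl <- log10(min(x[!z])) - 1
      out[z, j] <- fl
      floors[colnames(X)[j]] <- fl
    }
  }
  attr(out, "zero_floor") <- floors
  out
}

#' Pairwise Pearson correlations of feature columns
#'
#' Correlation-coefficient matrix of the log10 component concentrations
#' across combinations; components sourced from the same compound (Na/Cl,
#' NH4/SO4, K/PO4) show up as high-correlation blocks. Zero-variance
#' columns yield `NA` rows/columns.
#'
#' @param fm Feature matrix from [log_features()] (>= 3 rows).
#' @return Symmetric correlation matrix with unit diagonal (diagonal kept
#'   at 1 even for zero-variance columns).
#' @export
feature_correlations <- function(fm) {
  if (nrow(fm) < 3L) stop("need >= 3 rows")
  suppressWarnings(cc <- stats::cor(fm, method = "pearson"))
  diag(cc) <- 1
  cc
}

#' An M63-like base media combination
#'
#' Single-row [media_table()] at the base recipe used as the reference
#' point of the design: 22.4 mM glucose, 31.6 mM (NH4)2SO4 (63.2 mM NH4),
#' phosphate buffer at the 5:3 ratio, 1 mM MgSO4, trace thiamine and iron.
#'
#' @return A [media_table()] with one combination `"M63"`.
#' @export
media_m63 <- function() {
  df <- data.frame(
    combination_id = "M63", glucose = 22.4, `(NH4)2SO4` = 31.6,
    K2HPO4 = 62.5, KH2PO4 = 37.5, MgSO4 = 1, thiamine_HCl = 0.003,
    FeSO4 = 0.0045, NaCl = 0, leucine = 0, histidine = 0,
    check.names = FALSE, stringsAsFactors = FALSE)
  media_table(df, ratio_lock = TRUE)
}
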