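# Wavelet feature construction: four per-residue descriptor groups are read
# as short digital signals and summarised by DWT energy/entropy descriptors
# (11 per group) and level-3 WPT descriptors (22 per group), expanding the 43
# traditional columns to 175.

.group_columns <- function() {
  list(
    ASA  = traditional_columns("asa_mono"),
    uASA = traditional_columns("asa_comp"),
    dASA = traditional_columns("asa_delta"),
    DSSP = traditional_columns("dssp")
  )
}

.dwt_descriptors <- c("ea1", "ea2", "ea3", "ea_std", "ea_mean", "ed",
                      "shannon", "log_energy", "threshold", "sure", "norm")
.wpt_descriptors <- c(paste0("rel_e", 0:7), paste0("abs_e", 0:7), "abs_sum",
                      "shannon", "log_energy", "threshold", "sure", "norm")

#' Names of the 132 wavelet-derived feature columns
#'
#' 44 DWT columns followed by 88 WPT columns, named
#' `{group}_{transform}_{descriptor}` with groups in fixed order
#' ASA, uASA, dASA, DSSP.
#'
#' @return character vector of length 132.
#' @export
wavelet_feature_names <- function() {
  groups <- names(.group_columns())
  c(
    unlist(lapply(groups, function(g) paste0(g, "_dwt_", .dwt_descriptors))),
    unlist(lapply(groups, function(g) paste0(g, "_wpt_", .wpt_descriptors)))
  )
}

#' Build the four signal groups of a residue
#'
#' Extracts, in canonical column order, the four descriptor groups that are
#' treated as digital-signal channels: monomer-state solvent accessibility
#' (ASA, length 8), complex-state (uASA, 8), their relative change (dASA, 8),
#' and the secondary-structure block (DSSP, 6). Depth/protrusion and
#' hydrogen-bond columns are not part of any signal group.
#'
#' @param record a `residue_record`, or a named numeric vector containing the
#'   43 canonical traditional features.
#' @return named list of 4 numeric vectors, in order ASA, uASA, dASA, DSSP.
#' @export
build_signal_groups <- function(record) {
  values <- if (inherits(record, "residue_record")) record$traditional
            else record
  if (is.null(names(values))) {
    stop("traditional features must be named", call. = FALSE)
  }
  missing <- setdiff(traditional_columns(), names(values))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(.group_columns(), function(cols) unname(values[cols]))
}

.check_groups <- function(groups) {
  want <- names(.group_columns())
  if (is.null(names(groups)) || !setequal(names(groups), want)) {
    stop("groups must be a named list with exactly the names ",
         paste(want, collapse = ", "), " (positional input is rejected)",
         call. = FALSE)
  }
  groups <- groups[want]
  lens <- c(ASA = 8L, uASA = 8L, dASA = 8L, DSSP = 6L)
  for (g in want) {
    if (length(groups[[g]]) != lens[[g]]) {
      stop("group ", g, " must have length ", lens[[g]], call. = FALSE)
    }
    if (all(groups[[g]] == 0)) {
      stop("group ", g, " is all-zero: wavelet energy percentages undefined",
           call. = FALSE)
    }
  }
  groups
}

#' DWT feature block (44 values) for the four signal groups
#'
#' Per group, 11 descriptors in fixed order: the three per-level
#' approximation energy percentages, their population standard deviation and
#' mean, the detail energy percentage, then the five wavelet entropies of the
#' concatenated DWT coefficients (approximation level 3, details 3, 2, 1).
#'
#' @param groups named list as produced by [build_signal_groups()].
#' @return named numeric vector of 44 feature values.
#' @export
dwt_features <- function(groups) {
  groups <- .check_groups(groups)
  out <- lapply(names(groups), function(g) {
    d <- dwt_multilevel(groups[[g]], levels = 3L)
    es <- dwt_energy_summary(d)
    coeffs <- c(d$approx[[3]], d$detail[[3]], d$detail[[2]], d$detail[[1]])
    v <- c(es$ea, es$ea_std, es$ea_mean, es$ed, entropy_vector(coeffs))
    names(v) <- paste0(g, "_dwt_", .dwt_descriptors)
    v
  })
  unlist(out)
}

#' WPT feature block (88 values) for the four signal groups
#'
#' Per group, 22 descriptors in fixed order: relative energies of the 8
#' terminal sub-bands, their absolute energies, the absolute energy sum, then
#' the five wavelet entropies of the concatenated terminal-node coefficients.
#'
#' @param groups named list as produced by [build_signal_groups()].
#' @return named numeric vector of 88 feature values.
#' @export
wpt_features <- function(groups) {
  groups <- .check_groups(groups)
  out <- lapply(names(groups), function(g) {
    w <- wpt_level3(groups[[g]])
    es <- wpt_energy_summary(w)
    coeffs <- unlist(w$nodes)
    v <- c(es$relative, es$absolute, es$total, entropy_vector(coeffs))
    names(v) <- paste0(g, "_wpt_", .wpt_descriptors)
    v
  })
  unlist(out)
}

#' Expand a traditional table to the full 175-column feature table
#'
#' Row-wise and deterministic: each residue's 43 traditional descriptors are
#' kept and augmented with 44 DWT and 88 WPT wavelet features. Labels and
#' metadata are carried through unchanged; row order is preserved.
#'
#' @param ft a `feature_table` at stage `"traditional"`.
#' @return a `feature_table` at stage `"full175"` with 175 feature columns.
#' @export
featurize_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$stage != "traditional") {
    stop("featurize_table expects a traditional-stage table", call. = FALSE)
  }
  validate_feature_table(ft)
  n <- nrow(ft$features)
  wnames <- wavelet_feature_names()
  wav <- matrix(NA_real_, nrow = n, ncol = length(wnames),
                dimnames = list(NULL, wnames))
  for (i in seq_len(n)) {
    row <- unlist(ft$features[i, , drop = FALSE])
    groups <- tryCatch(.check_groups(build_signal_groups(row)),
                       error = function(e) {
                         stop("row ", i, ": ", conditionMessage(e),
                              call. = FALSE)
                       })
    wav[i, ] <- c(dwt_features(groups), wpt_features(groups))
  }
  feats <- cbind(ft$features, as.data.frame(wav))
  feature_table(feats, labels = ft$labels, meta = ft$meta, stage = "full175")
}
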