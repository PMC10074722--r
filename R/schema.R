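# Data model for per-residue interface descriptors and tabular I/O.
#
# The 43 "traditional" descriptors come from four structure tools whose
# numeric outputs are consumed as table columns (the tools themselves are
# never run here): NACCESS solvent accessibility (24), DSSP secondary
# structure (6), PSAIA depth/protrusion indices (12) and an HBPLUS
# hydrogen-bond count (1). The canonical column order below is fixed by this
# package so that downstream signal construction is deterministic.

.asa_attrs <- c("all", "nonpolar", "polar", "side")

.block_asa <- function(state) {
  c(paste0("asa_", .asa_attrs, "_", state), paste0("rsa_", .asa_attrs, "_", state))
}

# TCO (carbonyl angle cosine), KAPPA (bond angle), ALPHA/PHI/PSI (torsions),
# water-molecule count.
.block_dssp <- c("dssp_tco", "dssp_kappa", "dssp_alpha", "dssp_phi",
                 "dssp_psi", "dssp_water")

.block_dpx_cx <- c(
  "dpx_mean_bound", "dpx_mean_unbound", "dpx_sd_bound", "dpx_sd_unbound",
  "cx_mean_bound", "cx_mean_unbound", "cx_sd_bound", "cx_sd_unbound",
  "dpx_mean_delta", "dpx_sd_delta", "cx_mean_delta", "cx_sd_delta"
)

#' Canonical names of the 43 traditional feature columns
#'
#' The ordered column vocabulary the whole pipeline is built on: 24
#' solvent-accessibility features (absolute and relative ASA for four atomic
#' property classes, in monomer state, complex state, and their relative
#' change), 6 secondary-structure features, 12 depth/protrusion (DPX/CX)
#' features, and one hydrogen-bond count.
#'
#' @param block optional block selector: `"asa_mono"`, `"asa_comp"`,
#'   `"asa_delta"`, `"dssp"`, `"dpx_cx"`, `"hbond"`, or `"all"` (default).
#' @return character vector of column names in canonical order.
#' @export
#' @examples
#' length(traditional_columns())  # 43
#' traditional_columns("dssp")
traditional_columns <- function(block = "all") {
  blocks <- list(
    asa_mono  = .block_asa("mono"),
    asa_comp  = .block_asa("comp"),
    asa_delta = .block_asa("delta"),
    dssp      = .block_dssp,
    dpx_cx    = .block_dpx_cx,
    hbond     = "hbond_count"
  )
  if (identical(block, "all")) return(unname(unlist(blocks)))
  if (!block %in% names(blocks)) {
    stop("unknown block '", block, "'", call. = FALSE)
  }
  blocks[[block]]
}

.meta_columns <- c("pdb_id", "chain", "position", "wt_residue", "ddg")

#' Names of the 175 columns of the full feature table
#'
#' The 43 traditional columns followed by 44 DWT-derived and 88 WPT-derived
#' wavelet columns, in the fixed order produced by [featurize_table()].
#'
#' @return character vector of length 175.
#' @export
full175_columns <- function() {
  c(traditional_columns(), wavelet_feature_names())
}

#' Construct a feature table
#'
#' The central container passed between pipeline stages: a numeric feature
#' block, optional binary labels, optional residue metadata, and a schema
#' stage tag. Stages `"traditional"` (exactly the 43 canonical columns) and
#' `"full175"` (the 175 canonical columns) are validated strictly;
#' `"selected"` accepts any non-empty set of uniquely named numeric columns.
#'
#' @param features data.frame or matrix of numeric feature columns.
#' @param labels optional binary vector (1 = hot spot) aligned to rows.
#' @param meta optional data.frame of residue identity columns; recognised
#'   names are `pdb_id`, `chain`, `position`, `wt_residue`, `ddg`.
#' @param stage schema stage: `"traditional"`, `"full175"` or `"selected"`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(features, labels = NULL, meta = NULL,
                          stage = c("traditional", "full175", "selected")) {
  stage <- match.arg(stage)
  features <- as.data.frame(features, optional = TRUE)
  ft <- structure(
    list(features = features, labels = labels, meta = meta, stage = stage),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

#' Validate a feature table against its stage schema
#'
#' Checks column identity and order for the strict stages, numeric finite
#' values everywhere, label alignment, and the hydrogen-bond count being a
#' non-negative integer-valued column where present. Missing values are
#' rejected, never imputed.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  f <- ft$features
  expected <- switch(ft$stage,
    traditional = traditional_columns(),
    full175 = full175_columns(),
    selected = NULL
  )
  if (!is.null(expected)) {
    missing <- setdiff(expected, names(f))
    if (length(missing)) {
      stop("schema error: missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(f), expected)
    if (length(extra)) {
      stop("schema error: unexpected column(s) for stage '", ft$stage, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (!identical(names(f), expected)) {
      ft$features <- f <- f[expected]   # enforce canonical order
    }
  } else {
    if (ncol(f) < 1L) stop("schema error: no feature columns", call. = FALSE)
    if (anyDuplicated(names(f))) {
      stop("schema error: duplicated column names", call. = FALSE)
    }
  }
  for (cn in names(f)) {
    v <- f[[cn]]
    if (!is.numeric(v)) {
      stop("parse error: non-numeric values in feature column '", cn, "'",
           call. = FALSE)
    }
    if (nrow(f) && any(!is.finite(v))) {
      stop("parse error: non-finite value in column '", cn, "' at row ",
           which(!is.finite(v))[1L], call. = FALSE)
    }
  }
  if (!is.null(ft$labels)) {
    if (length(ft$labels) != nrow(f)) {
      stop("labels must have one entry per row", call. = FALSE)
    }
    if (length(ft$labels) && !all(ft$labels %in% c(0, 1))) {
      stop("labels must be binary 0/1", call. = FALSE)
    }
  }
  if (!is.null(ft$meta)) {
    if (nrow(ft$meta) != nrow(f)) {
      stop("meta must have one row per feature row", call. = FALSE)
    }
    unknown <- setdiff(names(ft$meta), .meta_columns)
    if (length(unknown)) {
      stop("unknown metadata column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> stage=%s, %d rows x %d feature columns\n",
              x$stage, nrow(x$features), ncol(x$features)))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(x$labels == 1), sum(x$labels == 0)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Construct a single residue record
#'
#' One mutated interface residue: identity, binding free-energy change, and
#' the 43 traditional descriptors.
#'
#' @param pdb_id 4-character structure identifier.
#' @param chain chain identifier.
#' @param position integer residue number.
#' @param wt_residue one-letter wild-type amino-acid code.
#' @param ddg binding free-energy change on mutation, kcal/mol.
#' @param traditional named numeric vector with exactly the canonical 43
#'   entries (see [traditional_columns()]).
#' @param label optional binary label; defaults to [label_from_ddg()] of
#'   `ddg`.
#' @return object of class `residue_record`.
#' @export
residue_record <- function(pdb_id, chain, position, wt_residue, ddg,
                           traditional, label = NULL) {
  if (!is.character(pdb_id) || nchar(pdb_id) != 4L) {
    stop("pdb_id must be a 4-character identifier", call. = FALSE)
  }
  if (!is.finite(ddg)) stop("ddg must be finite", call. = FALSE)
  cn <- traditional_columns()
  if (is.null(names(traditional)) || !setequal(names(traditional), cn) ||
      length(traditional) != 43L) {
    stop("traditional must be a named vector with exactly the 43 canonical ",
         "feature names", call. = FALSE)
  }
  traditional <- traditional[cn]
  if (any(!is.finite(traditional))) {
    stop("all traditional feature values must be finite", call. = FALSE)
  }
  hb <- traditional[["hbond_count"]]
  if (hb < 0 || hb != round(hb)) {
    stop("hbond_count must be a non-negative integer count", call. = FALSE)
  }
  if (is.null(label)) label <- label_from_ddg(ddg)
  structure(
    list(pdb_id = pdb_id, chain = as.character(chain),
         position = as.integer(position), wt_residue = as.character(wt_residue),
         ddg = as.numeric(ddg), traditional = traditional,
         label = as.integer(label)),
    class = "residue_record"
  )
}

#' Hot-spot labeling rule
#'
#' A mutated interface residue is a hot spot when its binding free-energy
#' change is at least 1.0 kcal/mol; the boundary value 1.0 itself is a hot
#' spot.
#'
#' @param ddg binding free-energy change(s), kcal/mol; must be finite.
#' @return integer vector of labels, 1 = hot spot, 0 = non-hot spot.
#' @export
#' @examples
#' label_from_ddg(c(1.0, 0.999, -2.5))  # 1 0 0
label_from_ddg <- function(ddg) {
  if (!is.numeric(ddg) || any(!is.finite(ddg))) {
    stop("ddg must be finite numeric", call. = FALSE)
  }
  as.integer(ddg >= 1.0)
}

#' Read a feature table from CSV or TSV
#'
#' The delimiter (comma or tab) is auto-detected from the header line.
#' Recognised metadata columns (`pdb_id`, `chain`, `position`, `wt_residue`,
#' `ddg`) and a `label` column are split off; the remaining columns must
#' match the declared stage schema. Row order is preserved.
#'
#' @param path file path.
#' @param stage schema stage, as in [feature_table()].
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path,
                               stage = c("traditional", "full175", "selected")) {
  stage <- match.arg(stage)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, na.strings = character(0))
  meta_present <- intersect(.meta_columns, names(df))
  meta <- if (length(meta_present)) df[meta_present] else NULL
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df[["label"]]
    df[["label"]] <- NULL
  }
  feats <- df[setdiff(names(df), meta_present)]
  if (nrow(feats) == 0L) feats[] <- lapply(feats, as.numeric)
  # locate any non-numeric cell precisely before type coercion can hide it
  for (cn in names(feats)) {
    v <- feats[[cn]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("parse error: non-numeric value '", v[bad[1L]], "' in column '",
             cn, "' at row ", bad[1L], call. = FALSE)
      }
      feats[[cn]] <- num
    }
  }
  feature_table(feats, labels = labels, meta = meta, stage = stage)
}

#' Write a feature table to CSV
#'
#' Columns are written as metadata, then features in canonical order, then
#' the `label` column if labels are present. Numeric values are written with
#' 17 significant digits so that [read_feature_table()] inverts the write to
#' full double precision.
#'
#' @param ft a valid `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  validate_feature_table(ft)
  out <- list()
  if (!is.null(ft$meta)) {
    m <- as.list(ft$meta)
    if (!is.null(m$ddg)) m$ddg <- sprintf("%.17g", m$ddg)
    out <- c(out, m)
  }
  fchar <- lapply(ft$features, function(v) sprintf("%.17g", v))
  out <- c(out, fchar)
  if (!is.null(ft$labels)) out$label <- as.integer(ft$labels)
  df <- as.data.frame(out, optional = TRUE, check.names = FALSE)
  # 0-row tables still need a header line
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(ft$features)) {
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Bundle a train/test split
#'
#' @param train,test labelled `feature_table` objects.
#' @return object of class `dataset_split`.
#' @export
dataset_split <- function(train, test) {
  for (part in list(train, test)) {
    if (is.null(part$labels)) {
      stop("both splits must carry labels", call. = FALSE)
    }
  }
  structure(list(train = train, test = test), class = "dataset_split")
}

#' Class bookkeeping for a train/test split
#'
#' Counts positives and negatives per split and the positive:negative ratio,
#' the quantity conventionally reported alongside benchmark hot-spot data
#' sets (e.g. 101/170 training residues give ratio 0.594).
#'
#' @param split a `dataset_split`.
#' @return data.frame with one row per split: `n_pos`, `n_neg`, `ratio`, and
#'   `ratio_fmt` (ratio formatted to three decimals).
#' @export
split_summary <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  one <- function(ft) {
    if (is.null(ft$labels)) stop("labels missing", call. = FALSE)
    n_pos <- sum(ft$labels == 1)
    n_neg <- sum(ft$labels == 0)
    data.frame(n_pos = n_pos, n_neg = n_neg, ratio = n_pos / n_neg,
               ratio_fmt = sprintf("%.3f", n_pos / n_neg))
  }
  out <- rbind(one(split$train), one(split$test))
  rownames(out) <- c("train", "test")
  out
}

# Run code with a local RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
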