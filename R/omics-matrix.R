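#' Construct an OmicsMatrix
#'
#' Light-weight container for one ome's feature-by-sample values together with
#' feature metadata and a missingness mask. Missing cells are stored as `NA`
#' in `values`; the mask is derived, never stored separately, so the two can
#' not drift apart.
#'
#' @param values Numeric matrix, features in rows (unique rownames required),
#'   samples in columns (colnames required). Counts for count omes
#'   (`rna`, `atac`), log-ratios for `protein`/`phospho`, abundances for
#'   `metab`.
#' @param ome One of `"rna"`, `"atac"`, `"protein"`, `"phospho"`, `"metab"`.
#' @param features Optional data.frame of per-feature metadata (gene symbol,
#'   peak coordinates, phosphosite id, ...). Row order must match `values`.
#' @param check_counts Enforce non-negativity for count omes (`rna`,
#'   `atac`). Disable for matrices already on the log scale.
#' @return An object of class `OmicsMatrix` with elements `values`, `ome`,
#'   `features`.
#' @export
omics_matrix <- function(values, ome, features = NULL,
                         check_counts = TRUE) {
  ome <- match.arg(ome, c("rna", "atac", "protein", "phospho", "metab"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (feature ids)")
  if (is.null(colnames(values)))
    stop("`values` must have colnames (sample ids)")
  if (check_counts && ome %in% c("rna", "atac") &&
      any(values < 0, na.rm = TRUE))
    stop("count ome '", ome, "' contains negative values")
  if (is.null(features)) {
    features <- data.frame(feature_id = rownames(values),
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features)
    if (nrow(features) != nrow(values))
      stop("`features` must have one row per feature")
  }
  rownames(features) <- rownames(values)
  structure(list(values = values, ome = ome, features = features),
            class = "OmicsMatrix")
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' @export
dimnames.OmicsMatrix <- function(x) dimnames(x$values)

#' Missingness mask of an OmicsMatrix
#'
#' @param m An `OmicsMatrix`.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(m) {
  stopifnot(inherits(m, "OmicsMatrix"))
  is.na(m$values)
}

#' Subset an OmicsMatrix
#'
#' @param x An `OmicsMatrix`.
#' @param i,j Feature / sample indices (any form accepted by matrix indexing).
#' @param ... Ignored.
#' @export
`[.OmicsMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  omics_matrix(x$values[i, j, drop = FALSE], x$ome,
               x$features[i, , drop = FALSE], check_counts = FALSE)
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples (%.1f%% missing)\n",
              x$ome, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

GROUPS <- c("CON", "EE", "RE")
TIMEPOINTS <- c("pre", "15min", "3.5h", "24h")
POST_TIMEPOINTS <- c("15min", "3.5h", "24h")
ARMS <- c("Early", "Middle", "Late", "All")

#' Validate a sample design table
#'
#' The design table governs all model fits and contrasts. Checks: required
#' columns; every participant has exactly one pre sample; (participant,
#' timepoint) unique; groups and timepoints from the fixed vocabulary.
#'
#' @param design data.frame with columns `sample_id`, `participant_id`,
#'   `group`, `timepoint`, `sex`, `age`, `batch`.
#' @return The design, invisibly, with `group`/`timepoint` as factors in
#'   canonical order. Errors describe the first violated invariant.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "participant_id", "group", "timepoint",
            "sex", "age", "batch")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  if (!all(design$group %in% GROUPS))
    stop("group values must be one of ", paste(GROUPS, collapse = "/"))
  if (!all(design$timepoint %in% TIMEPOINTS))
    stop("timepoint values must be one of ", paste(TIMEPOINTS, collapse = "/"))
  key <- paste(design$participant_id, design$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (participant, timepoint) rows in design")
  pre_n <- table(design$participant_id[design$timepoint == "pre"])
  all_p <- unique(design$participant_id)
  if (!all(all_p %in% names(pre_n)))
    stop("every participant must have exactly one pre sample")
  design$group <- factor(design$group, levels = GROUPS)
  design$timepoint <- factor(design$timepoint, levels = TIMEPOINTS)
  invisible(design)
}

## internal: derive a fresh integer seed stream from a base seed, bounded
## below 2^31 so it is always a valid R integer
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

## internal: run expr under a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## internal: BH adjustment within strata of a long table
bh_within <- function(p, strata) {
  adj <- rep(NA_real_, length(p))
  for (s in split(seq_along(p), strata)) {
    adj[s] <- stats::p.adjust(p[s], method = "BH")
  }
  adj
}
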