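## fixed profile cell order for fold-change profiles
PROFILE_CELLS <- c("EE_15min", "EE_3.5h", "EE_24h",
                   "RE_15min", "RE_3.5h", "RE_24h")

#' Assemble delta-delta fold-change profiles for phosphosites
#'
#' One profile per site: the difference-in-changes estimates over the fixed
#' (modality, timepoint) order EE-15min, EE-3.5h, EE-24h, RE-15min,
#' RE-3.5h, RE-24h. Cells without a computed contrast are `NA`. Also
#' reports whether each site is differentially abundant (adjusted p < 0.05)
#' at one or more cells.
#'
#' @param results Tidy contrast table (see [differential_analysis()]) for
#'   the phospho ome.
#' @param site_ids Optional subset of sites.
#' @return List of class `FoldChangeProfiles`: `profiles` (sites x 6
#'   matrix), `da` (named logical).
#' @export
profile_fold_changes <- function(results, site_ids = NULL) {
  r <- results
  if (!is.null(site_ids)) r <- r[r$feature_id %in% site_ids, , drop = FALSE]
  cells <- paste(r$group, r$timepoint, sep = "_")
  sites <- sort(unique(r$feature_id))
  prof <- matrix(NA_real_, length(sites), length(PROFILE_CELLS),
                 dimnames = list(sites, PROFILE_CELLS))
  keep <- cells %in% PROFILE_CELLS
  prof[cbind(match(r$feature_id[keep], sites),
             match(cells[keep], PROFILE_CELLS))] <- r$estimate[keep]
  da <- tapply(r$adj_p < 0.05, r$feature_id, any)
  da <- stats::setNames(as.logical(da[sites]), sites)
  da[is.na(da)] <- FALSE
  structure(list(profiles = prof, da = da), class = "FoldChangeProfiles")
}

#' Nearest-neighbor phosphosites of an anchor site
#'
#' Pairwise-complete Pearson correlation of each site's fold-change profile
#' with the anchor's (at least `min_overlap` shared cells); neighbors are
#' sites with `r >= r_min` that are also differentially abundant at one or
#' more cells (when `require_da`). The anchor is excluded from its own
#' neighbor set; all-constant profiles are skipped and logged in the
#' `"skipped"` attribute.
#'
#' @param anchor Anchor site id (must be present; error otherwise).
#' @param fcp A `FoldChangeProfiles` object.
#' @param r_min Correlation threshold (0.8).
#' @param require_da Require DA at >= 1 (modality, timepoint).
#' @param min_overlap Minimum shared non-missing cells (3).
#' @return data.frame `site_id`, `r`, `da` of the neighbor set, ordered by
#'   decreasing r.
#' @export
find_neighbors <- function(anchor, fcp, r_min = 0.8, require_da = TRUE,
                           min_overlap = 3) {
  prof <- fcp$profiles
  if (!anchor %in% rownames(prof))
    stop("anchor site '", anchor, "' absent from the profiles")
  a <- prof[anchor, ]
  skipped <- character()
  rs <- rep(NA_real_, nrow(prof))
  for (i in seq_len(nrow(prof))) {
    b <- prof[i, ]
    both <- !is.na(a) & !is.na(b)
    if (sum(both) < min_overlap) next
    if (stats::sd(b[both]) == 0 || stats::sd(a[both]) == 0) {
      skipped <- c(skipped, rownames(prof)[i])
      next
    }
    rs[i] <- stats::cor(a[both], b[both])
  }
  names(rs) <- rownames(prof)
  sel <- !is.na(rs) & rs >= r_min & names(rs) != anchor
  if (require_da) sel <- sel & fcp$da[names(rs)]
  out <- data.frame(site_id = names(rs)[sel], r = rs[sel],
                    da = fcp$da[names(rs)[sel]],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Protein-level ORA of a neighbor site set
#'
#' Sites are collapsed to their proteins; the universe is all quantified
#' sites' proteins; hypergeometric over-representation with BH adjustment.
#' Sets are reported when they contain at least `min_proteins` contributing
#' (overlapping) proteins and have adjusted p < `alpha`.
#'
#' @param neighbors Character vector of neighbor site ids.
#' @param universe_sites All quantified site ids.
#' @param site_protein Named vector site_id -> protein/gene id.
#' @param sets Named list of protein-level sets.
#' @param min_proteins Minimum contributing proteins for reporting (5).
#' @param alpha Reporting threshold on adjusted p (0.05).
#' @return data.frame from [ora()] with a `reported` flag column.
#' @export
neighbor_ora <- function(neighbors, universe_sites, site_protein, sets,
                         min_proteins = 5, alpha = 0.05) {
  universe <- unique(stats::na.omit(site_protein[universe_sites]))
  hits <- unique(stats::na.omit(site_protein[neighbors]))
  if (!length(hits)) {
    out <- data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(),
                      adj_p = numeric(), reported = logical())
    return(out)
  }
  out <- ora(hits, universe, sets)
  out$reported <- out$overlap >= min_proteins & out$adj_p < alpha
  out
}
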