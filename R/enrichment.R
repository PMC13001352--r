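#' Convert moderated t statistics to z-scores
#'
#' Two-sided, sign-preserving normal-quantile transform of the t CDF at the
#' fitted degrees of freedom: `z = qnorm(pt(t, df))`, computed on the log
#' scale in the tails for numerical stability.
#'
#' @param t Moderated t statistics.
#' @param df Degrees of freedom (scalar or vector).
#' @return z-scores with the same signs as `t`.
#' @export
t_to_z <- function(t, df) {
  df <- rep_len(df, length(t))
  z <- numeric(length(t))
  neg <- t <= 0
  ## work in the lower tail of |t| to keep log-probabilities accurate
  z[neg] <- stats::qnorm(stats::pt(t[neg], df[neg], log.p = TRUE),
                         log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df[!neg], log.p = TRUE),
                           log.p = TRUE)
  z
}

#' Build a z-score matrix from contrast results
#'
#' Maps features to identifiers (gene symbols, metabolite subclass ids or
#' phosphosite flanking ids), converts moderated t to z, and collapses
#' multiple features per identifier within each contrast to the single
#' entry of maximum absolute value (ties broken toward the first feature in
#' sorted id order). Unmapped features are dropped with a count recorded in
#' the `"n_unmapped"` attribute.
#'
#' @param results Tidy contrast table from [differential_analysis()] (or a
#'   compatible table with `feature_id`, `contrast`, `t`, `df_total`).
#' @param feature_map Named character vector feature_id -> identifier.
#' @return Matrix of z-scores, rows = identifiers, columns = contrasts;
#'   `NA` where an identifier was not tested in a contrast.
#' @export
build_zscore_matrix <- function(results, feature_map = NULL) {
  if (is.null(feature_map)) {
    feature_map <- stats::setNames(unique(results$feature_id),
                                   unique(results$feature_id))
  }
  id <- unname(feature_map[results$feature_id])
  n_unmapped <- sum(is.na(id))
  keep <- !is.na(id)
  r <- results[keep, , drop = FALSE]
  id <- id[keep]
  z <- t_to_z(r$t, r$df_total)
  contrasts <- unique(r$contrast)
  ids <- sort(unique(id))
  out <- matrix(NA_real_, length(ids), length(contrasts),
                dimnames = list(ids, contrasts))
  ## sorted feature order makes the max-|z| tie-break deterministic
  ord <- order(r$contrast, id, r$feature_id)
  for (i in ord) {
    cur <- out[id[i], r$contrast[i]]
    if (is.na(cur) || abs(z[i]) > abs(cur))
      out[id[i], r$contrast[i]] <- z[i]
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Split multi-site phosphosite rows into single sites
#'
#' Ids of the form `protein_S1;S2` are expanded into one row per single
#' site (`protein_S1`, `protein_S2`) with identical row information.
#' Duplicated single sites within a contrast are resolved to the entry of
#' maximum absolute z (or of the `value_col` given).
#'
#' @param tab data.frame with a `site_id` column and a statistic column.
#' @param value_col Name of the statistic column used for deduplication.
#' @return data.frame of single-site rows.
#' @export
split_multisite <- function(tab, value_col = "z") {
  pat <- "^(.+)_(p?[STY][0-9]+(;p?[STY][0-9]+)*)$"
  bad <- !grepl(pat, tab$site_id)
  if (any(bad))
    stop("unparseable phosphosite id(s): ",
         paste(unique(tab$site_id[bad]), collapse = ", "))
  protein <- sub(pat, "\\1", tab$site_id)
  sites <- strsplit(sub(pat, "\\2", tab$site_id), ";", fixed = TRUE)
  n <- lengths(sites)
  out <- tab[rep(seq_len(nrow(tab)), n), , drop = FALSE]
  out$site_id <- paste0(rep(protein, n), "_", unlist(sites))
  ## deduplicate within contrast (if present): keep max |value|
  strata <- if ("contrast" %in% names(out))
    paste(out$site_id, out$contrast) else out$site_id
  ord <- order(strata, -abs(out[[value_col]]),
               rep(seq_len(nrow(tab)), n))
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(strata[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a gene-set collection against a measured universe
#'
#' Members are intersected with the universe; sets with fewer than
#' `min_size` surviving members are dropped, and gene sets (not metabolite
#' or kinase collections) are additionally dropped when less than
#' `min_retained` of their original members survive.
#'
#' @param sets Named list of character vectors.
#' @param universe Identifiers present in the analysis.
#' @param min_size Minimum surviving set size (5).
#' @param min_retained Minimum survival fraction for gene sets (0.70).
#' @param is_gene_sets Apply the retention rule (TRUE for gene sets).
#' @return Filtered named list.
#' @export
filter_sets <- function(sets, universe, min_size = 5, min_retained = 0.70,
                        is_gene_sets = TRUE) {
  if (!length(universe)) stop("empty universe")
  out <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- vapply(seq_along(out), function(i) {
    surv <- length(out[[i]])
    if (surv < min_size) return(FALSE)
    if (is_gene_sets &&
        surv / length(unique(sets[[i]])) < min_retained) return(FALSE)
    TRUE
  }, logical(1))
  out[keep]
}

#' Pre-ranked CAMERA gene-set test
#'
#' Competitive set test on a vector of z-scores: the standardized
#' difference between the set mean and the non-set mean, with the set-mean
#' variance inflated by `VIF = 1 + (m-1)*rho` for inter-feature correlation
#' `rho`; two-sided p from a t distribution on G-2 df. BH is applied across
#' the collection; flag threshold is 0.05 (raised to 0.10 for kinase
#' collections via `alpha`).
#'
#' @param z Named numeric vector of z-scores (one contrast column).
#' @param sets Named list of member id vectors.
#' @param rho Assumed inter-feature correlation (0.01).
#' @param alpha Significance threshold on adjusted p (0.05; use 0.10 for
#'   kinase sets).
#' @return data.frame: `set`, `n`, `statistic`, `direction`, `p`, `adj_p`,
#'   `significant`. Sets equal to the universe are reported as `NA`.
#' @export
camera_pr <- function(z, sets, rho = 0.01, alpha = 0.05) {
  z <- z[is.finite(z)]
  G <- length(z)
  stat_all <- var(z)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(z))
    m <- length(members)
    m2 <- G - m
    if (m < 2 || m2 < 2) {
      return(data.frame(set = nm, n = m, statistic = NA_real_,
                        direction = NA_character_, p = NA_real_))
    }
    vif <- 1 + (m - 1) * rho
    mean_set <- mean(z[members])
    mean_all <- mean(z)
    delta <- G / m2 * (mean_set - mean_all)
    var_pooled <- ((G - 1) * stat_all - delta^2 * m * m2 / G) / (G - 2)
    var_pooled <- max(var_pooled, 1e-12)
    tstat <- delta / sqrt(var_pooled * (vif / m + 1 / m2))
    data.frame(set = nm, n = m, statistic = tstat,
               direction = if (tstat >= 0) "up" else "down",
               p = 2 * stats::pt(-abs(tstat), df = G - 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out
}

#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation p from the hypergeometric tail,
#' BH-adjusted across sets.
#'
#' @param hits Character vector of selected identifiers (subset of
#'   `universe`).
#' @param universe All tested identifiers.
#' @param sets Named list of member id vectors.
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `adj_p`.
#' @export
ora <- function(hits, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(intersect(hits, universe))
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(hits, s))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(hits), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out
}

## unweighted running-sum enrichment score: area under the running
## enrichment statistic over all list positions
running_sum_es <- function(stat_sorted_members, N) {
  ## stat_sorted_members: logical membership in rank order
  m <- sum(stat_sorted_members)
  step <- ifelse(stat_sorted_members, 1 / m, -1 / (N - m))
  mean(cumsum(step))
}

#' Directional PTM signature enrichment (single-site running sum)
#'
#' For each signature, members tagged `"d"` have the feature statistic
#' sign-flipped before ranking (a down signature should score positively
#' when its sites decrease); features are ranked by the (signed) statistic
#' in decreasing order; the running sum rises `1/m` at members and falls
#' `1/(G-m)` elsewhere (unit weights); the enrichment score is the mean of
#' the running statistic over positions (area statistic). NES divides ES by
#' the mean |ES| of same-sign scores over `nperm` feature-label
#' permutations; p is the smoothed same-sign permutation tail.
#'
#' @param z Named numeric vector of single-site z-scores.
#' @param signatures Named list of member vectors, entries `"id;u"` /
#'   `"id;d"` (untagged means `"u"`).
#' @param nperm Number of feature-label permutations (1000).
#' @param min_overlap Minimum members present in the data (5); smaller
#'   signatures are skipped.
#' @param seed RNG seed for the permutations.
#' @return data.frame: `signature`, `n_overlap`, `es`, `nes`, `p`, `adj_p`;
#'   skipped signatures are absent.
#' @export
ptm_sea <- function(z, signatures, nperm = 1000, min_overlap = 5,
                    seed = 1L) {
  if (nperm < 1) stop("nperm must be >= 1")
  z <- z[is.finite(z)]
  N <- length(z)
  res <- lapply(names(signatures), function(nm) {
    dir <- parse_directional_set(signatures[[nm]])
    dir <- dir[dir$id %in% names(z), , drop = FALSE]
    dir <- dir[!duplicated(dir$id), , drop = FALSE]
    m <- nrow(dir)
    if (m < min_overlap || m >= N) return(NULL)
    zz <- z
    flip <- dir$id[dir$direction == "d"]
    zz[flip] <- -zz[flip]
    memb <- names(zz) %in% dir$id
    ord <- order(zz, decreasing = TRUE)
    es <- running_sum_es(memb[ord], N)
    ## permutation null: random member labels on the same ranked list
    perm_es <- with_seed(derive_seed(seed, utf8ToInt(substr(nm, 1, 1)) +
                                            nchar(nm)), {
      vapply(seq_len(nperm), function(i) {
        pm <- logical(N)
        pm[sample.int(N, m)] <- TRUE
        running_sum_es(pm, N)
      }, numeric(1))
    })
    same <- perm_es[sign(perm_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(signature = nm, n_overlap = m, es = es, nes = nes, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(signature = character(), n_overlap = integer(),
                      es = numeric(), nes = numeric(), p = numeric(),
                      adj_p = numeric()))
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Localization-confidence filter for phosphosites
#'
#' @param site_meta data.frame with `site_id` and `confident_score`.
#' @param cutoff Minimum confidence score (sites kept when score > cutoff).
#' @return Character vector of confidently localized site ids.
#' @export
confident_sites <- function(site_meta, cutoff = 17) {
  site_meta$site_id[site_meta$confident_score > cutoff]
}
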