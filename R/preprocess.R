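#' Default feature-filter rule for an ome
#'
#' Encodes the per-ome inclusion rules used throughout the pipeline:
#' \itemize{
#'   \item `rna`: remove genes having <= `cpm_threshold` (0.5) counts per
#'     million in at least `sample_frac` (10\%) of samples. This is the
#'     literal reading of the rule; `reading = "keep_expressed"` instead
#'     keeps genes with CPM > 0.5 in more than 10\% of samples (the common
#'     alternative reading). Both are available because the literal rule is
#'     extremely aggressive on sparse data.
#'   \item `atac`: keep peaks with at least `min_count` (10) reads in at
#'     least `min_samples` (6) samples.
#'   \item `protein` / `phospho`: remove features quantified in less than
#'     `min_frac` (30\%) of samples.
#'   \item `metab`: remove features with more than `max_missing` (20\%)
#'     missing values.
#' }
#'
#' @param ome Ome label.
#' @param ... Overrides for the rule parameters listed above.
#' @return A list of class `FilterRule`.
#' @export
filter_rule <- function(ome, ...) {
  defaults <- switch(ome,
    rna = list(cpm_threshold = 0.5, sample_frac = 0.1, reading = "literal"),
    atac = list(min_count = 10, min_samples = 6),
    protein = ,
    phospho = list(min_frac = 0.30),
    metab = list(max_missing = 0.20),
    stop("unknown ome label: ", ome))
  over <- list(...)
  defaults[names(over)] <- over
  structure(c(list(ome = ome), defaults), class = "FilterRule")
}

#' Apply an ome-specific feature filter
#'
#' @param m An [omics_matrix()].
#' @param rule A [filter_rule()] for the same ome (default rule when `NULL`).
#' @return Named logical keep-mask over features.
#' @export
filter_features <- function(m, rule = NULL) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (is.null(rule)) rule <- filter_rule(m$ome)
  if (!identical(rule$ome, m$ome))
    stop("rule is for ome '", rule$ome, "', matrix is '", m$ome, "'")
  x <- m$values
  keep <- switch(m$ome,
    rna = {
      counts <- x
      counts[is.na(counts)] <- 0
      lib <- colSums(counts)
      cpm <- sweep(counts, 2, pmax(lib, 1), "/") * 1e6
      if (identical(rule$reading, "literal")) {
        ## remove genes with CPM <= threshold in at least sample_frac of
        ## samples
        low <- rowMeans(cpm <= rule$cpm_threshold)
        low < rule$sample_frac
      } else {
        rowMeans(cpm > rule$cpm_threshold) > rule$sample_frac
      }
    },
    atac = {
      counts <- x
      counts[is.na(counts)] <- 0
      rowSums(counts >= rule$min_count) >= rule$min_samples
    },
    protein = ,
    phospho = rowMeans(!is.na(x)) >= rule$min_frac,
    metab = rowMeans(is.na(x)) <= rule$max_missing)
  names(keep) <- rownames(x)
  keep
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Library scaling factors from doubly trimmed between-sample log-ratios:
#' per sample, M-values against a reference library are trimmed by
#' `logratio_trim` (30\% each tail) and A-values by `sum_trim` (5\% each
#' tail); the factor is the precision-weighted mean of the surviving
#' M-values. Factors are geometric-mean centered so they multiply to 1.
#'
#' @param counts Count matrix (features x samples), no negative entries.
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A.
#' @param ref Optional reference sample (index or name); default is the
#'   sample whose CPM upper quartile is closest to the mean upper quartile.
#' @return Numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        ref = NULL) {
  counts[is.na(counts)] <- 0
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample library: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  }
  yr <- counts[, ref]
  lr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    ok <- y > 0 & yr > 0
    if (!any(ok)) return(1)
    M <- log2((y[ok] / lib[j]) / (yr[ok] / lr))
    A <- 0.5 * log2((y[ok] / lib[j]) * (yr[ok] / lr))
    ## asymptotic (delta-method) variance of M
    v <- (lib[j] - y[ok]) / (lib[j] * y[ok]) + (lr - yr[ok]) / (lr * yr[ok])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' log2 counts per million with a 0.5 offset
#'
#' @param counts Count matrix.
#' @param factors TMM scaling factors (default: computed).
#' @param prior_count Offset added to counts before log (voom convention).
#' @return Matrix of log2-CPM values; TMM factors and effective library
#'   sizes attached as attributes.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  counts[is.na(counts)] <- 0
  if (is.null(factors)) factors <- tmm_factors(counts)
  lib <- colSums(counts) * factors
  out <- log2(t((t(counts) + prior_count) / (lib + 1)) * 1e6)
  attr(out, "tmm_factors") <- factors
  attr(out, "lib_size") <- lib
  out
}

#' Ome-appropriate normalization
#'
#' Counts (rna/atac) get TMM factors followed by log2-CPM; protein and
#' phospho log-ratios are median-centered per sample (medians exactly zero
#' afterwards); metabolite abundances are log2(x+1)-transformed, then
#' median-MAD scaled per sample when neither the sample medians nor the
#' upper quartiles are associated with sex or group (Kruskal-Wallis
#' p < 0.01) -- i.e. scaling is skipped when it could erase a biological
#' signal.
#'
#' @param m An [omics_matrix()] (post-filter).
#' @param design Optional design table; needed for the metabolite
#'   association test (`mad_scale = "auto"`).
#' @param mad_scale `"auto"`, `"always"` or `"never"` (metabolites only).
#' @param mad_constant MAD scale constant (1.4826 for normal consistency).
#' @return A normalized `OmicsMatrix`; count omes carry `tmm_factors` in
#'   the attributes of `$values`.
#' @export
normalize_omics <- function(m, design = NULL,
                            mad_scale = c("auto", "always", "never"),
                            mad_constant = 1.4826) {
  stopifnot(inherits(m, "OmicsMatrix"))
  mad_scale <- match.arg(mad_scale)
  x <- m$values
  out <- switch(m$ome,
    rna = ,
    atac = log_cpm(x),
    protein = ,
    phospho = sweep(x, 2, apply(x, 2, stats::median, na.rm = TRUE)),
    metab = {
      lx <- log2(x + 1)
      do_mad <- mad_scale == "always"
      if (mad_scale == "auto" && !is.null(design)) {
        med <- apply(lx, 2, stats::median, na.rm = TRUE)
        uq <- apply(lx, 2, stats::quantile, probs = 0.75, na.rm = TRUE)
        grp <- interaction(design$group, design$timepoint, drop = TRUE)
        ps <- c(tryCatch(stats::kruskal.test(med, factor(design$sex))$p.value,
                         error = function(e) 1),
                tryCatch(stats::kruskal.test(uq, factor(design$sex))$p.value,
                         error = function(e) 1),
                tryCatch(stats::kruskal.test(med, grp)$p.value,
                         error = function(e) 1),
                tryCatch(stats::kruskal.test(uq, grp)$p.value,
                         error = function(e) 1))
        do_mad <- all(ps >= 0.01)
      }
      if (do_mad) {
        med <- apply(lx, 2, stats::median, na.rm = TRUE)
        madv <- apply(lx, 2, stats::mad, constant = mad_constant,
                      na.rm = TRUE)
        madv[madv == 0] <- 1
        sweep(sweep(lx, 2, med), 2, madv, "/")
      } else lx
    })
  res <- omics_matrix(out, m$ome, m$features, check_counts = FALSE)
  attributes(res$values) <- attributes(out)
  res
}

#' Impute missing metabolite values
#'
#' K-nearest-neighbor imputation over features for matrices with more than
#' 12 features, half-minimum imputation otherwise (each missing cell set to
#' half the feature's observed minimum).
#'
#' @param m A filtered metabolite [omics_matrix()] (<= 20\% missing per
#'   feature).
#' @param k Number of neighbor features for KNN.
#' @return The `OmicsMatrix` with no missing cells.
#' @export
impute_metabolites <- function(m, k = 5) {
  stopifnot(inherits(m, "OmicsMatrix"))
  x <- m$values
  if (!anyNA(x)) return(m)
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("feature(s) entirely missing (should have been filtered): ",
         paste(rownames(x)[all_missing], collapse = ", "))
  if (nrow(x) > 12) {
    ## KNN on features: distance over mutually observed samples, scaled rows
    xs <- t(scale(t(x)))
    for (f in which(rowSums(is.na(x)) > 0)) {
      miss <- which(is.na(x[f, ]))
      d <- vapply(seq_len(nrow(x)), function(g) {
        if (g == f) return(Inf)
        both <- !is.na(xs[f, ]) & !is.na(xs[g, ])
        if (sum(both) < 3) return(Inf)
        sqrt(mean((xs[f, both] - xs[g, both])^2))
      }, numeric(1))
      for (s in miss) {
        ## candidates must be observed in the *original* data at sample s
        cand <- which(is.finite(d) & !is.na(xs[, s]))
        if (!length(cand)) { x[f, s] <- min(x[f, ], na.rm = TRUE) / 2; next }
        nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
        w <- 1 / (d[nb] + 1e-8)
        ## impute on the feature's own scale via scaled-neighbor average
        mu_f <- mean(x[f, ], na.rm = TRUE); sd_f <- stats::sd(x[f, ], na.rm = TRUE)
        if (!is.finite(sd_f) || sd_f == 0) sd_f <- 1
        zs <- vapply(nb, function(g) xs[g, s], numeric(1))
        x[f, s] <- mu_f + sd_f * sum(w * zs) / sum(w)
      }
    }
  } else {
    for (f in seq_len(nrow(x))) {
      miss <- is.na(x[f, ])
      if (any(miss)) x[f, miss] <- min(x[f, ], na.rm = TRUE) / 2
    }
  }
  omics_matrix(x, m$ome, m$features)
}

#' Flag sample outliers on principal components
#'
#' Runs PCA on samples and flags any sample whose score on a retained
#' component lies outside `[Q1 - k*IQR, Q3 + k*IQR]` (boxplot whiskers
#' extended to `iqr_mult` times the interquartile range; default 5).
#'
#' @param m An [omics_matrix()] (missing cells mean-imputed per feature for
#'   the decomposition only).
#' @param iqr_mult Whisker multiplier `k`.
#' @param var_explained Keep the top components explaining this fraction of
#'   variance (default 0.95).
#' @param max_pc Upper bound on the number of components examined.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_pca_outliers <- function(m, iqr_mult = 5, var_explained = 0.95,
                                max_pc = 10) {
  stopifnot(inherits(m, "OmicsMatrix"))
  x <- m$values
  if (ncol(x) < 3) stop("need at least 3 samples for PCA outlier detection")
  ## mean-impute per feature, drop constant features
  for (f in seq_len(nrow(x))) {
    miss <- is.na(x[f, ])
    if (any(miss)) x[f, miss] <- mean(x[f, ], na.rm = TRUE)
  }
  x <- x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(x) == 0) stop("no variable features for PCA")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  nkeep <- min(max_pc, ncol(pc$x),
               which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= var_explained)[1])
  flagged <- logical(ncol(m$values))
  for (j in seq_len(nkeep)) {
    s <- pc$x[, j]
    q <- stats::quantile(s, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    flagged <- flagged | s < q[1] - iqr_mult * iqr | s > q[2] + iqr_mult * iqr
  }
  colnames(m$values)[flagged]
}

#' Regress technical covariates out of a normalized matrix
#'
#' Per feature, values are regressed on the column-bound protected design
#' and batch covariates; only the fitted batch component is subtracted, so
#' protected (biological) effects pass through untouched.
#'
#' @param m A normalized [omics_matrix()].
#' @param batch Numeric design matrix of technical covariates (samples x
#'   columns), e.g. `model.matrix(~ batch, design)[, -1, drop = FALSE]`.
#' @param protected Numeric design matrix of protected effects, e.g. from
#'   [protected_design_matrix()].
#' @return The adjusted `OmicsMatrix`.
#' @export
remove_batch_effects <- function(m, batch, protected) {
  stopifnot(inherits(m, "OmicsMatrix"))
  batch <- as.matrix(batch); protected <- as.matrix(protected)
  X <- cbind(protected, batch)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design + batch covariates are rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  bcols <- ncol(protected) + seq_len(ncol(batch))
  x <- m$values
  for (f in seq_len(nrow(x))) {
    y <- x[f, ]
    obs <- !is.na(y)
    if (sum(obs) <= ncol(X)) next
    beta <- qr.coef(qr(X[obs, , drop = FALSE]), y[obs])
    bb <- beta[bcols]
    bb[is.na(bb)] <- 0
    x[f, ] <- y - as.numeric(batch %*% bb)
  }
  omics_matrix(x, m$ome, m$features)
}

#' Protected design matrix for batch removal
#'
#' Cell-means coding of group x timepoint plus sex and age, mirroring the
#' design protected during technical-effect regression.
#'
#' @param design A validated design table.
#' @return Numeric model matrix (samples x columns).
#' @export
protected_design_matrix <- function(design) {
  design <- as.data.frame(validate_design(design))
  cell <- interaction(design$group, design$timepoint, drop = TRUE)
  stats::model.matrix(~ 0 + cell + sex + age, data =
    data.frame(cell = cell, sex = factor(design$sex), age = design$age))
}
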