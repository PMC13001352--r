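#' Eligibility filter for difference-in-changes analysis
#'
#' A feature is eligible when, for every group and every post-exercise
#' timepoint present in the design, at least `min_pairs` participants have
#' an observed pre sample and an observed sample at that timepoint.
#' Features failing the criterion anywhere are excluded from differential
#' analysis entirely.
#'
#' @param design Validated design table.
#' @param m An [omics_matrix()] aligned to `design$sample_id`.
#' @param min_pairs Minimum paired participants per group-timepoint (3).
#' @return Named logical vector over features.
#' @export
eligibility_filter <- function(design, m, min_pairs = 3) {
  stopifnot(inherits(m, "OmicsMatrix"))
  design <- as.data.frame(validate_design(design))
  x <- m$values[, design$sample_id, drop = FALSE]
  obs <- !is.na(x)
  post_tps <- intersect(POST_TIMEPOINTS, unique(as.character(design$timepoint)))
  pre_cols <- design$timepoint == "pre"
  elig <- rep(TRUE, nrow(x))
  for (g in GROUPS) {
    gpre <- pre_cols & design$group == g
    pre_obs <- obs[, gpre, drop = FALSE]
    colnames(pre_obs) <- design$participant_id[gpre]
    for (tp in post_tps) {
      gpost <- design$group == g & design$timepoint == tp
      if (!any(gpost)) { elig[] <- FALSE; next }
      post_obs <- obs[, gpost, drop = FALSE]
      colnames(post_obs) <- design$participant_id[gpost]
      shared <- intersect(colnames(pre_obs), colnames(post_obs))
      if (length(shared) < min_pairs) { elig[] <- FALSE; next }
      npair <- rowSums(pre_obs[, shared, drop = FALSE] &
                       post_obs[, shared, drop = FALSE])
      elig <- elig & npair >= min_pairs
    }
  }
  names(elig) <- rownames(x)
  elig
}

#' Cell-means fixed-effect design matrix
#'
#' One indicator column per observed group-by-timepoint cell, plus centered
#' covariate columns (factors expanded to treatment-coded dummies).
#'
#' @param design Validated design table.
#' @param covariates Character vector of covariate column names in `design`.
#' @return List with `X` (model matrix), `cells` (cell label per cell
#'   column), `n_cell_cols`.
#' @keywords internal
cell_means_design <- function(design, covariates = c("sex", "age", "batch")) {
  ## `design` may be a per-feature subset (observed rows only), so full
  ## design invariants are not re-checked here
  cell <- factor(paste(design$group, design$timepoint, sep = "."))
  Xc <- stats::model.matrix(~ 0 + cell)
  colnames(Xc) <- levels(cell)
  covlist <- list()
  for (cv in covariates) {
    v <- design[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not in design")
    if (is.numeric(v)) {
      d <- matrix(v - mean(v), ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      if (nlevels(f) > 1) {
        d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(d) <- paste0(cv, levels(f)[-1])
        d <- scale(d, scale = FALSE)
      } else {
        ## keep the constant column so rank-deficiency is reported, matching
        ## the skip-with-reason contract
        d <- matrix(1, nrow(design), 1,
                    dimnames = list(NULL, paste0(cv, levels(f)[1])))
      }
    }
    covlist[[cv]] <- d
  }
  X <- if (length(covlist)) cbind(Xc, do.call(cbind, covlist)) else Xc
  list(X = X, cells = colnames(Xc), n_cell_cols = ncol(Xc))
}

## --- REML engine: one random intercept, observation weights ---------------
## V = sigma_e^2 (W^{-1} + lambda Z Z'), Z = participant indicators.
## Blocks are per participant, so V^{-1} has a Sherman-Morrison closed form;
## all lambda-independent pieces are precomputed once per feature.
reml_precomp <- function(y, X, pid, w) {
  blocks <- split(seq_along(y), pid)
  p <- ncol(X)
  B <- length(blocks)
  U <- matrix(0, p, B)       # X_b' w_b per block
  yu <- numeric(B)           # y_b' w_b
  sw <- numeric(B)           # sum of w in block
  for (b in seq_len(B)) {
    i <- blocks[[b]]
    wb <- w[i]
    U[, b] <- crossprod(X[i, , drop = FALSE], wb)
    yu[b] <- sum(y[i] * wb)
    sw[b] <- sum(wb)
  }
  list(XtWX = crossprod(X, X * w), XtWy = crossprod(X, y * w),
       ytWy = sum(y^2 * w), U = U, yu = yu, sw = sw,
       sumlogw = sum(log(w)), n = length(y), p = p)
}

reml_solve <- function(lambda, pre) {
  c_b <- lambda * pre$sw / (1 + lambda * pre$sw)
  cs <- c_b / pre$sw   # lambda / (1 + lambda*sw): scales u u' terms
  A <- pre$XtWX - pre$U %*% (cs * t(pre$U))
  b <- pre$XtWy - pre$U %*% (cs * pre$yu)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), b))
  yy <- pre$ytWy - sum(cs * pre$yu^2)
  rss <- max(yy - sum(b * beta), 1e-12)
  df <- pre$n - pre$p
  s2 <- rss / df
  logdetV <- sum(log1p(lambda * pre$sw)) - pre$sumlogw
  logdetA <- 2 * sum(log(diag(R)))
  crit <- logdetV + logdetA + df * log(s2)
  list(beta = beta, R = R, s2 = s2, df = df, crit = crit)
}

#' Fit a per-feature cell-means mixed model
#'
#' REML with a single participant random intercept, profiled to a
#' one-dimensional search over the variance ratio; at the zero boundary the
#' fit collapses to weighted least squares. The unscaled cell-mean
#' covariance is retained for contrasts.
#'
#' @param y Named numeric vector of feature values (names = sample ids;
#'   `NA` allowed).
#' @param design Validated design table.
#' @param covariates Covariate columns of `design` to adjust for.
#' @param weights Optional per-observation weights aligned to
#'   `design$sample_id`.
#' @return List of class `cell_means_fit` with `cells` (named cell-mean
#'   estimates), `beta`, `cov_unscaled`, `s2`, `df`, `lambda`, `sigma_a2`,
#'   `n_used`; or a list with `skipped = TRUE` and a `reason` code when the
#'   observed design is singular.
#' @export
fit_cell_means <- function(y, design, covariates = c("sex", "age", "batch"),
                           weights = NULL) {
  design <- as.data.frame(validate_design(design))
  y <- y[design$sample_id]
  if (is.null(weights)) weights <- rep(1, nrow(design))
  obs <- !is.na(y)
  d <- design[obs, , drop = FALSE]
  d$timepoint <- droplevels(d$timepoint); d$group <- droplevels(d$group)
  cm <- tryCatch(cell_means_design(d, covariates), error = function(e) e)
  if (inherits(cm, "error"))
    return(list(skipped = TRUE, reason = conditionMessage(cm)))
  X <- cm$X
  if (qr(X)$rank < ncol(X))
    return(list(skipped = TRUE, reason = "singular"))
  yv <- y[obs]; w <- weights[obs]
  pre <- reml_precomp(yv, X, d$participant_id, w)
  if (pre$n - pre$p < 1)
    return(list(skipped = TRUE, reason = "no residual df"))
  crit_fun <- function(loglam) {
    fit <- reml_solve(exp(loglam), pre)
    if (is.null(fit)) return(1e30)
    fit$crit
  }
  opt <- stats::optimize(crit_fun, interval = c(log(1e-6), log(1e3)))
  at0 <- reml_solve(0, pre)
  if (is.null(at0)) return(list(skipped = TRUE, reason = "singular"))
  lambda <- if (at0$crit <= opt$objective) 0 else exp(opt$minimum)
  fit <- reml_solve(lambda, pre)
  cov_unscaled <- chol2inv(fit$R)
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(as.numeric(fit$beta), colnames(X))
  structure(list(cells = beta[cm$cells], beta = beta,
                 cov_unscaled = cov_unscaled, s2 = fit$s2, df = fit$df,
                 lambda = lambda, sigma_a2 = lambda * fit$s2,
                 n_used = pre$n, cell_names = cm$cells),
            class = "cell_means_fit")
}

#' Difference-in-changes ("delta-delta") contrast
#'
#' Estimate and unscaled SE of
#' `(mu[g,t] - mu[g,pre]) - (mu[CON,t] - mu[CON,pre])` from a cell-means
#' fit. The returned `se_unscaled` excludes the residual SD so that
#' empirical-Bayes moderation can rescale it; `se = sqrt(s2) * se_unscaled`.
#'
#' @param fit A `cell_means_fit`.
#' @param group `"EE"` or `"RE"`.
#' @param timepoint A post-exercise timepoint label.
#' @return List with `estimate`, `se`, `se_unscaled`, `t`, `df`.
#' @export
delta_delta_contrast <- function(fit, group, timepoint) {
  if (isTRUE(fit$skipped)) stop("fit was skipped: ", fit$reason)
  need <- c(paste(group, timepoint, sep = "."), paste(group, "pre", sep = "."),
            paste("CON", timepoint, sep = "."), "CON.pre")
  missing_cells <- setdiff(need, fit$cell_names)
  if (length(missing_cells))
    stop("missing cell(s) for contrast: ",
         paste(missing_cells, collapse = ", "))
  cvec <- stats::setNames(rep(0, length(fit$beta)), names(fit$beta))
  cvec[need] <- c(1, -1, -1, 1)
  est <- sum(cvec * fit$beta)
  se_u <- sqrt(as.numeric(t(cvec) %*% fit$cov_unscaled %*% cvec))
  se <- sqrt(fit$s2) * se_u
  list(estimate = est, se = se, se_unscaled = se_u,
       t = est / se, df = fit$df)
}

## --- empirical-Bayes variance moderation ----------------------------------

## Newton inversion of the trigamma function (monotone decreasing on (0,Inf))
trigamma_inverse <- function(x) {
  out <- x
  out[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  out[x < 1e-6] <- 1 / x[x < 1e-6]
  mid <- x <= 1e7 & x >= 1e-6
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Squeeze residual variances toward a common prior
#'
#' Fits a scaled inverse-chi-squared prior to per-feature residual
#' variances by matching moments of log variances (digamma/trigamma
#' equations), then returns posterior variances `(d0*s0^2 + df*s2)/(d0+df)`.
#'
#' @param s2 Per-feature residual variances.
#' @param df Per-feature residual degrees of freedom (scalar or vector).
#' @return List with `var_post`, `var_prior` (`s0^2`), `df_prior` (`d0`).
#' @export
squeeze_var <- function(s2, df) {
  n <- length(s2)
  if (n < 2) {
    warning("fewer than 2 features: no variance shrinkage applied")
    return(list(var_post = s2, var_prior = mean(s2), df_prior = 0))
  }
  df <- rep_len(df, n)
  ok <- s2 > 0 & df > 0
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e[ok])
  evar <- stats::var(e[ok]) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    var_post <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    ## no excess spread beyond chi-square sampling noise: infinite prior
    ## df; the common variance is estimated by the mean so that constant
    ## inputs are returned unchanged
    d0 <- Inf
    s02 <- mean(s2)
    var_post <- rep(s02, n)
  }
  list(var_post = var_post, var_prior = s02, df_prior = d0)
}

#' Moderate contrast statistics and adjust p-values
#'
#' Applies empirical-Bayes variance shrinkage across features, recomputes
#' moderated t statistics with `df + d0` degrees of freedom, and applies
#' Benjamini-Hochberg separately within each (ome, contrast) stratum.
#' Features are flagged significant at adjusted p < 0.05.
#'
#' @param results Long data.frame with one row per (feature, contrast):
#'   columns `feature_id`, `ome`, `group`, `timepoint`, `estimate`,
#'   `se_unscaled`, `s2`, `df`, `n_used`.
#' @return The table with `se`, `t`, `df_total`, `p`, `adj_p`,
#'   `significant` columns added.
#' @export
moderate_and_adjust <- function(results) {
  stopifnot(all(c("feature_id", "ome", "group", "timepoint", "estimate",
                  "se_unscaled", "s2", "df") %in% names(results)))
  out <- NULL
  for (ome in unique(results$ome)) {
    r <- results[results$ome == ome, , drop = FALSE]
    feat <- !duplicated(r$feature_id)
    sq <- squeeze_var(r$s2[feat],
                      stats::setNames(r$df[feat], r$feature_id[feat]))
    post <- stats::setNames(sq$var_post, r$feature_id[feat])
    d0 <- sq$df_prior
    r$var_post <- post[r$feature_id]
    r$se <- sqrt(r$var_post) * r$se_unscaled
    r$t <- r$estimate / r$se
    r$df_total <- if (is.finite(d0)) r$df + d0 else 1e6
    r$p <- 2 * stats::pt(-abs(r$t), df = r$df_total)
    out <- rbind(out, r)
  }
  out$adj_p <- bh_within(out$p, paste(out$ome, out$group, out$timepoint))
  out$significant <- out$adj_p < 0.05
  out
}

#' Precision weights from the mean-variance trend of log-counts
#'
#' Fits a per-feature linear model on log2-CPM, smooths the square-root
#' residual SD against mean log2 count with lowess, and returns inverse
#' squared predicted trend values at the fitted log-counts (the voom
#' construction). With fewer than 2 residual degrees of freedom all weights
#' are 1 and a warning is logged.
#'
#' @param counts Raw count matrix (features x samples).
#' @param design Validated design table.
#' @param covariates Covariates for the fixed-effect trend fit.
#' @param span Lowess span.
#' @return List with `logcpm` (matrix), `weights` (matrix, all > 0),
#'   `tmm_factors`.
#' @export
voom_weights <- function(counts, design, covariates = c("sex", "age", "batch"),
                         span = 0.5) {
  design <- as.data.frame(validate_design(design))
  counts <- counts[, design$sample_id, drop = FALSE]
  y <- log_cpm(counts)
  lib <- attr(y, "lib_size")
  cm <- cell_means_design(design, covariates)
  X <- cm$X
  keep_cols <- qr(X)$pivot[seq_len(qr(X)$rank)]
  X <- X[, keep_cols, drop = FALSE]
  n <- ncol(y)
  if (n - ncol(X) < 2) {
    warning("fewer than 2 residual df: voom weights set to 1")
    w <- matrix(1, nrow(y), n, dimnames = dimnames(y))
    return(list(logcpm = y, weights = w,
                tmm_factors = attr(y, "tmm_factors")))
  }
  fit <- stats::lm.fit(X, t(y))
  fitted_y <- t(fit$fitted.values)
  sigma <- sqrt(colSums(fit$residuals^2) / (n - ncol(X)))
  mean_logcount <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  lo <- stats::lowess(mean_logcount, sqrt(sigma), f = span)
  trend <- stats::approxfun(lo, rule = 2)
  fitted_logcount <- fitted_y + mean(log2(lib + 1)) - log2(1e6)
  w <- 1 / pmax(trend(fitted_logcount), 1e-6)^4
  w <- matrix(w, nrow(y), n, dimnames = dimnames(y))
  list(logcpm = y, weights = w, tmm_factors = attr(y, "tmm_factors"))
}

#' Per-feature difference-in-changes analysis for one ome
#'
#' End-to-end wrapper: eligibility filtering, optional voom-style precision
#' weights for count omes, per-feature cell-means mixed-model fits,
#' delta-delta contrasts of EE and RE vs CON at every post timepoint in the
#' design, empirical-Bayes moderation and per-contrast BH adjustment.
#'
#' @param m An [omics_matrix()]; raw counts for `rna`/`atac` (normalized
#'   internally), normalized values otherwise.
#' @param design Validated design table.
#' @param covariates Covariate columns of `design` (default sex, age,
#'   batch; dropped automatically when constant).
#' @param min_pairs Eligibility threshold (see [eligibility_filter()]).
#' @return Tidy data.frame, one row per (feature, contrast), with
#'   `ContrastResult` fields; skipped features recorded in the
#'   `"skipped"` attribute.
#' @export
differential_analysis <- function(m, design,
                                  covariates = c("sex", "age", "batch"),
                                  min_pairs = 3) {
  stopifnot(inherits(m, "OmicsMatrix"))
  design <- as.data.frame(validate_design(design))
  ## drop covariates that are constant in this design
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(design[[cv]])) > 1, logical(1))]
  elig <- eligibility_filter(design, m, min_pairs)
  if (!any(elig))
    stop("no features satisfy the paired-participant eligibility filter ",
         "(need >= ", min_pairs, " pairs per group and post timepoint)")
  x <- m$values[, design$sample_id, drop = FALSE]
  weights <- NULL
  if (m$ome %in% c("rna", "atac")) {
    vw <- voom_weights(x[elig, , drop = FALSE], design, covariates)
    x <- vw$logcpm
    weights <- vw$weights
    feats <- rownames(x)
  } else {
    feats <- rownames(x)[elig]
  }
  post_tps <- intersect(POST_TIMEPOINTS, unique(as.character(design$timepoint)))
  rows <- vector("list", length(feats))
  skipped <- character()
  for (i in seq_along(feats)) {
    f <- feats[i]
    w_f <- if (is.null(weights)) NULL else weights[f, ]
    fit <- fit_cell_means(x[f, ], design, covariates, w_f)
    if (isTRUE(fit$skipped)) {
      skipped <- c(skipped, stats::setNames(fit$reason, f))
      next
    }
    cons <- expand.grid(group = c("EE", "RE"), timepoint = post_tps,
                        stringsAsFactors = FALSE)
    rr <- lapply(seq_len(nrow(cons)), function(j) {
      ct <- tryCatch(
        delta_delta_contrast(fit, cons$group[j], cons$timepoint[j]),
        error = function(e) NULL)
      if (is.null(ct)) return(NULL)
      data.frame(feature_id = f, ome = m$ome, group = cons$group[j],
                 timepoint = cons$timepoint[j], estimate = ct$estimate,
                 se_unscaled = ct$se_unscaled, s2 = fit$s2, df = fit$df,
                 n_used = fit$n_used, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, rr)
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0)
    stop("no eligible features produced contrasts")
  res <- moderate_and_adjust(res)
  res$contrast <- paste(res$group, res$timepoint, sep = "_")
  attr(res, "skipped") <- skipped
  rownames(res) <- NULL
  res
}
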