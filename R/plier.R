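#' Build a cross-omic stacked matrix with cumulative scores
#'
#' Rows are proteins/genes present in every participating ome. When ATAC
#' participates, a gene needs at least one annotated promoter peak
#' (`"Promoter (<=1kb)"`) and its row is the cumulative (summed) normalized
#' accessibility over those peaks; when phospho participates, a protein row
#' is the cumulative phosphorylation score (sum over its sites). Each ome
#' block is z-scored per row over its own samples, then blocks are
#' concatenated column-wise.
#'
#' @param mats Named list of normalized [omics_matrix()] objects; names
#'   from `atac`, `rna`, `protein`, `phospho`. Feature metadata must carry
#'   `gene_id` (and `annotation` for atac).
#' @param omes Which omes to stack (default: the names of `mats`).
#' @param cumulative `"sum"` (literal cumulative score) or `"mean"`.
#' @return List of class `CrossOmicMatrix`: `Y` (rows = shared gene ids,
#'   columns = `ome:sample`), `blocks` (named list of column indices),
#'   `col_ome`, `col_sample`.
#' @export
build_cross_omic_matrix <- function(mats, omes = names(mats),
                                    cumulative = c("sum", "mean")) {
  cumulative <- match.arg(cumulative)
  agg <- function(x, by) {
    ## row-aggregate x by gene id
    g <- factor(by)
    out <- rowsum(x, g, na.rm = TRUE)
    if (cumulative == "mean")
      out <- out / as.vector(table(g)[rownames(out)])
    out
  }
  blocks <- list()
  for (ome in omes) {
    m <- mats[[ome]]
    if (is.null(m)) stop("ome '", ome, "' not supplied")
    x <- m$values
    gene <- switch(ome,
      rna = ,
      protein = m$features$gene_id,
      atac = {
        promoter <- m$features$annotation == "Promoter (<=1kb)"
        x <- x[promoter, , drop = FALSE]
        m$features$gene_id[promoter]
      },
      phospho = m$features$gene_id)
    if (ome %in% c("atac", "phospho")) x <- agg(x, gene)
    else rownames(x) <- gene
    blocks[[ome]] <- x
  }
  shared <- Reduce(intersect, lapply(blocks, rownames))
  if (!length(shared))
    stop("empty intersection of features across omes: ",
         paste(omes, collapse = ", "))
  zblocks <- lapply(names(blocks), function(ome) {
    x <- blocks[[ome]][shared, , drop = FALSE]
    x[is.na(x)] <- 0
    xz <- t(scale(t(x)))
    xz[!is.finite(xz)] <- 0
    colnames(xz) <- paste(ome, colnames(x), sep = ":")
    xz
  })
  Y <- do.call(cbind, zblocks)
  sizes <- vapply(zblocks, ncol, integer(1))
  idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  names(idx) <- names(blocks)
  structure(list(Y = Y, blocks = idx,
                 col_ome = rep(names(blocks), sizes),
                 col_sample = sub("^[^:]+:", "", colnames(Y))),
            class = "CrossOmicMatrix")
}

#' Count significant principal components by parallel analysis
#'
#' Number of leading singular values of `Y` exceeding the 95th percentile
#' of the corresponding singular values of column-permuted copies of `Y`
#' (entries permuted within each column). The recommended latent-variable
#' count is twice this number; when estimation is infeasible the fallback
#' LV count is 100.
#'
#' @param Y Numeric matrix.
#' @param nperm Number of permutations (20).
#' @param seed RNG seed.
#' @return List with `k` (significant PCs) and `num_lv` (2k, or 100 on
#'   fallback).
#' @export
estimate_num_pc <- function(Y, nperm = 20, seed = 1L) {
  if (!all(is.finite(Y))) stop("Y must be finite")
  d <- svd(Y, nu = 0, nv = 0)$d
  if (max(d) < 1e-10) stop("degenerate (rank 0) matrix")
  k <- tryCatch({
    perm_d <- with_seed(derive_seed(seed, 11L), {
      vapply(seq_len(nperm), function(i) {
        Yp <- apply(Y, 2, sample)
        svd(Yp, nu = 0, nv = 0)$d
      }, numeric(length(d)))
    })
    thresh <- apply(perm_d, 1, stats::quantile, probs = 0.95)
    exceed <- d > thresh
    ## leading run only: a buried "significant" value is noise
    if (!exceed[1]) 0L else which.min(c(exceed, FALSE)) - 1L
  }, error = function(e) NA_integer_)
  if (is.na(k)) return(list(k = NA_integer_, num_lv = 100L))
  list(k = k, num_lv = 2L * k)
}

## nonnegative lasso coordinate descent for one U column:
## min_u lambda1 ||z - C u||^2 + lambda3 sum(u), u >= 0
nn_lasso_col <- function(z, C, u, lambda1, lambda3, sweeps = 10) {
  cc <- colSums(C^2)
  r <- z - as.numeric(C %*% u)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (j in seq_along(u)) {
      if (cc[j] == 0) next
      rho <- sum(C[, j] * r) + cc[j] * u[j]
      unew <- max(0, (rho - lambda3 / (2 * lambda1)) / cc[j])
      if (unew != u[j]) {
        r <- r - C[, j] * (unew - u[j])
        delta <- max(delta, abs(unew - u[j]))
        u[j] <- unew
      }
    }
    if (delta < 1e-8) break
  }
  u
}

#' Pathway-guided latent-variable decomposition
#'
#' Block-coordinate minimization of
#' `||Y - ZB||^2 + lambda1 ||Z - CU||^2 + lambda2 ||B||^2 + lambda3 |U|_1`
#' with `U >= 0`: ridge closed forms for `Z` (features x K loadings) and
#' `B` (K x samples scores), nonnegative lasso coordinate descent for the
#' pathway weights `U` (pathways x K). SVD initialization; converged when
#' the relative objective change drops below `tol`. After convergence the
#' LV loading columns are normalized to unit norm with compensating scaling
#' of `B` and `U` (scale identifiability).
#'
#' @param Y Numeric matrix (features x samples), typically from
#'   [build_cross_omic_matrix()].
#' @param C Binary prior matrix (features x pathways); may have 0 columns.
#' @param K Number of latent variables.
#' @param lambda1,lambda2,lambda3 Penalties; default `0.1 * mean singular
#'   value` of `Y` each.
#' @param max_iter,tol Outer-iteration cap (200) and relative-objective
#'   tolerance (1e-5).
#' @return List of class `PlierModel`: `Z`, `B`, `U`, `C`, penalties and
#'   the objective `trace` (non-increasing across outer iterations).
#' @export
fit_plier <- function(Y, C = NULL, K, lambda1 = NULL, lambda2 = NULL,
                      lambda3 = NULL, max_iter = 200, tol = 1e-5) {
  if (is.null(C)) C <- matrix(0, nrow(Y), 0)
  C <- as.matrix(C)
  if (nrow(C) != nrow(Y)) stop("C rows must align with Y rows")
  sv <- svd(Y, nu = K, nv = K)
  msv <- mean(sv$d)
  if (is.null(lambda1)) lambda1 <- 0.1 * msv
  if (is.null(lambda2)) lambda2 <- 0.1 * msv
  if (is.null(lambda3)) lambda3 <- 0.1 * msv
  ds <- sqrt(sv$d[seq_len(K)])
  Z <- sv$u %*% diag(ds, K)
  B <- diag(ds, K) %*% t(sv$v)
  U <- matrix(0, ncol(C), K)
  has_prior <- ncol(C) > 0 && lambda1 > 0
  objective <- function() {
    sum((Y - Z %*% B)^2) + lambda1 * sum((Z - C %*% U)^2) +
      lambda2 * sum(B^2) + lambda3 * sum(U)
  }
  trace <- objective()
  for (it in seq_len(max_iter)) {
    ## Z: ridge toward CU
    Z <- (Y %*% t(B) + lambda1 * (C %*% U)) %*%
      solve(B %*% t(B) + lambda1 * diag(K))
    ## B: ridge regression of Y on Z
    B <- solve(crossprod(Z) + lambda2 * diag(K), crossprod(Z, Y))
    ## U: nonnegative lasso per LV column
    if (has_prior) {
      for (k in seq_len(K))
        U[, k] <- nn_lasso_col(Z[, k], C, U[, k], lambda1, lambda3)
    }
    obj <- objective()
    if (!is.finite(obj))
      stop("non-finite objective at iteration ", it)
    trace <- c(trace, obj)
    if (abs(trace[it] - obj) < tol * abs(trace[it])) break
  }
  ## unit-norm loadings; compensate in B (and U, which approximates Z)
  s <- sqrt(colSums(Z^2))
  s[s == 0] <- 1
  Z <- sweep(Z, 2, s, "/")
  B <- B * s
  U <- sweep(U, 2, s, "/")
  rownames(Z) <- rownames(Y); colnames(B) <- colnames(Y)
  if (ncol(C)) rownames(U) <- colnames(C)
  structure(list(Z = Z, B = B, U = U, C = C, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3, trace = trace),
            class = "PlierModel")
}

#' Within-subject significance of latent variables
#'
#' Per subject and ome, the LV score change from pre to a post timepoint is
#' computed; exercise-group deltas are compared with CON deltas by Welch's
#' t-test, per (LV, ome, modality, timepoint); BH is applied across the
#' full grid.
#'
#' @param model A `PlierModel` fitted on a [build_cross_omic_matrix()]
#'   result.
#' @param xom The `CrossOmicMatrix` the model was fitted on.
#' @param design Validated design table.
#' @return data.frame: `lv`, `ome`, `group`, `timepoint`, `delta_mean`,
#'   `con_mean`, `p`, `adj_p`.
#' @export
lv_significance <- function(model, xom, design) {
  design <- as.data.frame(validate_design(design))
  B <- model$B
  K <- nrow(B)
  post_tps <- intersect(POST_TIMEPOINTS, unique(as.character(design$timepoint)))
  sample_of <- function(part, tp)
    design$sample_id[design$participant_id == part & design$timepoint == tp]
  rows <- list()
  for (ome in names(xom$blocks)) {
    cols <- xom$blocks[[ome]]
    csamp <- xom$col_sample[cols]
    for (tp in post_tps) {
      deltas_by_group <- lapply(c("CON", "EE", "RE"), function(g) {
        parts <- unique(design$participant_id[design$group == g])
        d <- vapply(parts, function(p) {
          s_pre <- sample_of(p, "pre"); s_post <- sample_of(p, tp)
          i_pre <- match(s_pre, csamp); i_post <- match(s_post, csamp)
          if (length(i_pre) != 1 || length(i_post) != 1 ||
              is.na(i_pre) || is.na(i_post)) return(rep(NA_real_, K))
          B[, cols[i_post]] - B[, cols[i_pre]]
        }, numeric(K))
        matrix(d, nrow = K)
      })
      names(deltas_by_group) <- c("CON", "EE", "RE")
      for (g in c("EE", "RE")) {
        for (k in seq_len(K)) {
          dg <- deltas_by_group[[g]][k, ]
          dc <- deltas_by_group[["CON"]][k, ]
          dg <- dg[!is.na(dg)]; dc <- dc[!is.na(dc)]
          if (length(dg) < 2 || length(dc) < 2) next
          p <- if (stats::sd(dg) == 0 && stats::sd(dc) == 0) {
            if (mean(dg) == mean(dc)) 1 else 0
          } else tryCatch(stats::t.test(dg, dc)$p.value,
                          error = function(e) NA_real_)
          rows[[length(rows) + 1]] <-
            data.frame(lv = k, ome = ome, group = g, timepoint = tp,
                       delta_mean = mean(dg), con_mean = mean(dc), p = p,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Cross-ome correlation of a latent variable
#'
#' Correlates the per-sample LV scores of two ome blocks over their shared
#' sample ids.
#'
#' @param model A `PlierModel`.
#' @param xom The `CrossOmicMatrix` it was fitted on.
#' @param lv LV index.
#' @param ome1,ome2 Block names.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
lv_cross_correlation <- function(model, xom, lv, ome1, ome2) {
  c1 <- xom$blocks[[ome1]]; c2 <- xom$blocks[[ome2]]
  s1 <- xom$col_sample[c1]; s2 <- xom$col_sample[c2]
  shared <- intersect(s1, s2)
  stats::cor(model$B[lv, c1[match(shared, s1)]],
             model$B[lv, c2[match(shared, s2)]])
}
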