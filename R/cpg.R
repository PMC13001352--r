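#' Construct a CpG coverage object
#'
#' @param sites data.frame with `chrom` and `pos` (1-based, strictly
#'   increasing within chromosome).
#' @param meth,total Integer matrices (sites x samples) of methylated and
#'   total read counts; `meth <= total` everywhere.
#' @return List of class `CpGCoverage`.
#' @export
cpg_coverage <- function(sites, meth, total) {
  stopifnot(nrow(sites) == nrow(meth), identical(dim(meth), dim(total)))
  if (any(meth > total)) stop("methylated counts exceed total counts")
  ord_ok <- all(tapply(sites$pos, sites$chrom,
                       function(p) all(diff(p) > 0)))
  if (!isTRUE(ord_ok))
    stop("positions must be strictly increasing within chromosome")
  if (is.null(colnames(total)))
    colnames(total) <- paste0("s", seq_len(ncol(total)))
  colnames(meth) <- colnames(total)
  if (nrow(sites) > 0)
    rownames(meth) <- rownames(total) <- paste0(sites$chrom, ":", sites$pos)
  structure(list(sites = sites, meth = meth, total = total),
            class = "CpGCoverage")
}

#' Filter CpG sites by coverage
#'
#' A site is retained iff its total coverage is at least `min_cov` in at
#' least `min_frac` of the samples (a site covered in exactly 50\% of the
#' samples is retained: the rule removes sites covered in *less than*
#' half).
#'
#' @param cov A `CpGCoverage`.
#' @param min_cov Minimum coverage (5).
#' @param min_frac Minimum fraction of samples (0.5).
#' @return The filtered `CpGCoverage`.
#' @export
filter_cpg_coverage <- function(cov, min_cov = 5, min_frac = 0.5) {
  stopifnot(inherits(cov, "CpGCoverage"))
  if (nrow(cov$sites) == 0) stop("empty CpG coverage input")
  keep <- rowMeans(cov$total >= min_cov) >= min_frac
  cpg_coverage(cov$sites[keep, , drop = FALSE],
               cov$meth[keep, , drop = FALSE],
               cov$total[keep, , drop = FALSE])
}

#' Markov Cluster Algorithm on a nonnegative weighted graph
#'
#' Self-loops (weight = max incident edge weight, so clustering is
#' invariant to uniform rescaling of all weights) are added for stability;
#' the column-stochastic matrix is then alternately expanded (matrix
#' power), inflated (elementwise power and renormalization) and pruned
#' below `prune` until the change drops under `tol`. Clusters are the
#' weakly connected components of the attractor graph. Fully
#' deterministic.
#'
#' @param adj Symmetric nonnegative weight matrix.
#' @param inflation Inflation exponent (2).
#' @param expansion Expansion power (2).
#' @param prune Entries below this are zeroed each iteration (1e-5).
#' @param max_iter Iteration cap (200); non-convergence returns the best
#'   iterate with a warning.
#' @param tol Convergence threshold on the max entry change (1e-6).
#' @return Integer cluster labels named by node.
#' @export
mcl <- function(adj, inflation = 2, expansion = 2, prune = 1e-5,
                max_iter = 200, tol = 1e-6) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj < 0)) stop("adjacency weights must be nonnegative")
  n <- nrow(adj)
  if (is.null(rownames(adj)))
    rownames(adj) <- colnames(adj) <- paste0("n", seq_len(n))
  M <- adj
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalize_cols <- function(x) sweep(x, 2, colSums(x), "/")
  M <- normalize_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mprev <- M
    Me <- M
    for (e in seq_len(expansion - 1)) Me <- Me %*% M
    Me <- Me^inflation
    Me[Me < prune] <- 0
    M <- normalize_cols(Me)
    if (max(abs(M - Mprev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; returning best-iterate clusters")
  g <- igraph::graph_from_adjacency_matrix((M > 1e-8) | t(M > 1e-8),
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), rownames(adj))
}

#' Merge nearby correlated CpG sites into regions
#'
#' Implements the four-step decision algorithm: (a) per sample, compute
#' `nCpG10`, the number of sites with at least 10x coverage; (b) exclude
#' samples below the 20th percentile of `nCpG10` from clustering; (c) build
#' a graph over sites with at least 10x coverage in all remaining samples,
#' connecting sites within `window_bp` on the same chromosome with the
#' Pearson correlation of their methylation fractions as edge weight
#' (negative correlations zeroed), and cluster it with [mcl()]; (d) apply
#' the resulting region assignment to all samples, including the excluded
#' ones. Sites not clusterable in (c) become singleton regions, and
#' clusters are split into runs of consecutive sites so region members are
#' always contiguous in the site ordering. The whole path is deterministic.
#'
#' @param cov A filtered `CpGCoverage`.
#' @param window_bp Proximity window in bp (> 0; default 1000 -- the merge
#'   window is a free parameter of this implementation and is logged in
#'   the output).
#' @param inflation MCL inflation (2).
#' @param min_cov10 Coverage threshold for steps (a) and (c) (10).
#' @param pct Percentile for sample exclusion (0.20).
#' @return List of class `CpGRegions`: `regions` (data.frame `region_id`,
#'   `chrom`, `start`, `end`, `n_sites`), `assignment` (region per site),
#'   `pooled_meth` / `pooled_total` (region x all-samples matrices),
#'   `excluded_samples`, `window_bp`.
#' @export
merge_cpg_regions <- function(cov, window_bp = 1000, inflation = 2,
                              min_cov10 = 10, pct = 0.20) {
  stopifnot(inherits(cov, "CpGCoverage"))
  if (window_bp <= 0) stop("window_bp must be positive")
  ncpg10 <- colSums(cov$total >= min_cov10)
  cutoff <- stats::quantile(ncpg10, pct)
  excluded <- colnames(cov$total)[ncpg10 < cutoff]
  use <- setdiff(colnames(cov$total), excluded)
  clusterable <- rowSums(cov$total[, use, drop = FALSE] >= min_cov10) ==
    length(use)

  nS <- nrow(cov$sites)
  assignment <- integer(nS)
  cl_idx <- which(clusterable)
  if (length(cl_idx) >= 2) {
    frac <- cov$meth[cl_idx, use, drop = FALSE] /
      pmax(cov$total[cl_idx, use, drop = FALSE], 1)
    k <- length(cl_idx)
    adj <- matrix(0, k, k,
                  dimnames = list(rownames(cov$meth)[cl_idx],
                                  rownames(cov$meth)[cl_idx]))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        si <- cl_idx[i]; sj <- cl_idx[j]
        if (cov$sites$chrom[si] != cov$sites$chrom[sj]) next
        if (abs(cov$sites$pos[si] - cov$sites$pos[sj]) > window_bp) next
        r <- suppressWarnings(stats::cor(frac[i, ], frac[j, ]))
        if (is.finite(r) && r > 0) adj[i, j] <- adj[j, i] <- r
      }
    }
    cl <- mcl(adj, inflation = inflation)
    assignment[cl_idx] <- cl
  } else if (length(cl_idx) == 1) {
    assignment[cl_idx] <- 1L
  }
  ## unclusterable sites become singletons; then enforce contiguity by
  ## splitting region labels at any interruption in the site ordering
  nxt <- max(assignment, 0L)
  for (i in which(assignment == 0L)) assignment[i] <- (nxt <- nxt + 1L)
  run_id <- cumsum(c(TRUE, assignment[-1] != assignment[-nS] |
                             cov$sites$chrom[-1] != cov$sites$chrom[-nS]))
  assignment <- match(run_id, unique(run_id))

  region_id <- sprintf("region%04d", assignment)
  pooled_meth <- rowsum(cov$meth, region_id)
  pooled_total <- rowsum(cov$total, region_id)
  regions <- do.call(rbind, lapply(split(seq_len(nS), region_id),
    function(ix) data.frame(chrom = cov$sites$chrom[ix[1]],
                            start = min(cov$sites$pos[ix]),
                            end = max(cov$sites$pos[ix]),
                            n_sites = length(ix))))
  regions <- data.frame(region_id = rownames(regions), regions,
                        stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 assignment = stats::setNames(region_id,
                                              rownames(cov$meth)),
                 pooled_meth = pooled_meth, pooled_total = pooled_total,
                 excluded_samples = excluded, window_bp = window_bp),
            class = "CpGRegions")
}
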