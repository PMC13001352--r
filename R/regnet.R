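#' Prepare the phospho-TF regulator matrix
#'
#' Filters phosphosites to those on transcription factors with at most
#' `max_missing` missing values, then completes the matrix by chained-
#' equations imputation run `n_imputations` times (seeds 1..n) and
#' averaged.
#'
#' @param phospho Normalized phospho [omics_matrix()]; feature metadata
#'   must carry `gene_id`.
#' @param tf_genes Character vector of TF gene ids.
#' @param max_missing Maximum missing fraction per site (0.40).
#' @param n_imputations Number of imputations averaged (15).
#' @return List of class `RegulatorMatrix`: `values` (complete matrix),
#'   `meta` (site_id, gene_id).
#' @export
prepare_regulators <- function(phospho, tf_genes, max_missing = 0.40,
                               n_imputations = 15) {
  stopifnot(inherits(phospho, "OmicsMatrix"))
  if (!length(tf_genes)) stop("tf_genes must be nonempty")
  on_tf <- phospho$features$gene_id %in% tf_genes
  ok_miss <- rowMeans(is.na(phospho$values)) <= max_missing
  keep <- on_tf & ok_miss
  if (!any(keep))
    stop("no TF phosphosites survive the ", 100 * max_missing,
         "% missingness filter")
  x <- phospho$values[keep, , drop = FALSE]
  if (anyNA(x)) {
    acc <- 0
    for (s in seq_len(n_imputations)) acc <- acc + mice_impute(x, seed = s)
    x <- acc / n_imputations
  }
  structure(list(values = x,
                 meta = data.frame(
                   site_id = rownames(x),
                   gene_id = phospho$features$gene_id[keep],
                   stringsAsFactors = FALSE)),
            class = "RegulatorMatrix")
}

#' Chained-equations imputation of a feature-by-sample matrix
#'
#' A compact multiple-imputation-by-chained-equations engine: variables are
#' features; each incomplete feature is regressed on its most correlated
#' complete-enough features and missing cells are drawn from the predictive
#' distribution (fitted value + Gaussian residual noise), sweeping all
#' incomplete features `n_iter` times. One call is one imputation; average
#' several calls with different seeds for the final values.
#'
#' @param x Numeric matrix (features x samples) with `NA`s.
#' @param seed RNG seed for this imputation.
#' @param n_iter Chained-equation sweeps (5).
#' @param n_pred Number of predictor features per incomplete feature (5).
#' @return Completed matrix.
#' @export
mice_impute <- function(x, seed = 1L, n_iter = 5, n_pred = 5) {
  with_seed(derive_seed(seed, 17L), {
    miss <- is.na(x)
    if (!any(miss)) return(x)
    ## initialize with row means
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (f in which(rowSums(miss) > 0)) x[f, miss[f, ]] <- rm_[f]
    incomplete <- which(rowSums(miss) > 0)
    cors <- suppressWarnings(stats::cor(t(x)))
    diag(cors) <- 0
    cors[!is.finite(cors)] <- 0
    pred_of <- lapply(incomplete, function(f) {
      ord <- order(abs(cors[f, ]), decreasing = TRUE)
      ord[seq_len(min(n_pred, length(ord)))]
    })
    names(pred_of) <- as.character(incomplete)
    for (it in seq_len(n_iter)) {
      for (f in sample(incomplete)) {
        preds <- pred_of[[as.character(f)]]
        obs <- !miss[f, ]
        X <- cbind(1, t(x[preds, , drop = FALSE]))
        fit <- stats::lm.fit(X[obs, , drop = FALSE], x[f, obs])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        sigma <- sqrt(sum(fit$residuals^2) /
                        max(1, sum(obs) - length(beta)))
        mi <- miss[f, ]
        x[f, mi] <- as.numeric(X[mi, , drop = FALSE] %*% beta) +
          stats::rnorm(sum(mi), 0, sigma)
      }
    }
    x
  })
}

#' Fuzzifier estimate for fuzzy c-means
#'
#' Closed-form estimator of the fuzzifier `m` from the data dimensions
#' (N features, D profile length):
#' `m = 1 + (1418/N + 22.05) D^-2 +
#'      (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param N Number of features.
#' @param D Profile length.
#' @return The fuzzifier `m` (> 1).
#' @export
estimate_fuzzifier <- function(N, D) {
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

## one fuzzy c-means run; deterministic under seed
fcm <- function(x, c, m, max_iter = 100, tol = 1e-6, seed = 1L) {
  N <- nrow(x)
  centroids <- with_seed(derive_seed(seed, 23L + c),
                         x[sample.int(N, c), , drop = FALSE])
  u <- matrix(1 / c, N, c)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rep(1, N), rep(0, c))
    for (k in seq_len(c))
      d2[, k] <- rowSums(sweep(x, 2, centroids[k, ])^2)
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-1 / (m - 1))
    unew <- inv / rowSums(inv)
    um <- unew^m
    centroids <- (t(um) %*% x) / colSums(um)
    if (max(abs(unew - u)) < tol) { u <- unew; break }
    u <- unew
  }
  list(membership = u, centroids = centroids)
}

#' Cluster regulator and target profiles by fuzzy c-means
#'
#' The stacked regulator/target z-profiles are scaled by row standard
#' deviations computed with two temporarily appended zero columns (the
#' implicit pre-exercise baselines), the fuzzifier comes from
#' [estimate_fuzzifier()], fuzzy c-means is run over `c_range`, and the
#' chosen cluster count is the largest `c` whose minimum pairwise centroid
#' distance exceeds `threshold_frac` of the distance at `c = 2` (minimum
#' centroid distance as validity index).
#'
#' @param profiles Numeric matrix (features x profile length), finite.
#' @param c_range Candidate cluster counts (default `2:8`).
#' @param threshold_frac Validity threshold as a fraction of the c = 2
#'   distance (0.1).
#' @param seed RNG seed for centroid initialization.
#' @return List: `membership` (rows sum to 1), `cluster` (argmax),
#'   `centroids`, `c`, `m`, `validity` (min centroid distance per c).
#' @export
cluster_features <- function(profiles, c_range = 2:8, threshold_frac = 0.1,
                             seed = 1L) {
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  N <- nrow(profiles)
  if (min(c_range) < 2 || max(c_range) > N - 1)
    stop("c_range must lie within [2, N-1]")
  sds <- apply(cbind(profiles, 0, 0), 1, stats::sd)
  sds[sds == 0] <- 1
  x <- profiles / sds
  m <- estimate_fuzzifier(N, ncol(profiles))
  fits <- list(); validity <- numeric(0)
  for (c in c_range) {
    fit <- fcm(x, c, m, seed = seed)
    dmin <- min(stats::dist(fit$centroids))
    fits[[as.character(c)]] <- fit
    validity[as.character(c)] <- dmin
  }
  ref <- validity[as.character(min(c_range))]
  ok <- c_range[validity > threshold_frac * ref]
  chosen <- if (length(ok)) max(ok) else min(c_range)
  fit <- fits[[as.character(chosen)]]
  cl <- apply(fit$membership, 1, which.max)
  names(cl) <- rownames(profiles)
  list(membership = fit$membership, cluster = cl,
       centroids = fit$centroids, c = chosen, m = m, validity = validity)
}

#' Infer regulator-to-target edges with tree-ensemble importances
#'
#' Per target gene, candidate regulators are the phosphosites sharing the
#' target's cluster (falling back to all regulators when none co-cluster),
#' minus any site on the target's own gene; an extremely-randomized-trees
#' regression of the target on the candidates yields normalized impurity
#' importances as edge weights.
#'
#' @param reg A `RegulatorMatrix` (or plain matrix) of regulators x
#'   samples.
#' @param targets Numeric matrix of target genes x samples (same columns).
#' @param clusters Optional named integer vector of cluster labels for
#'   regulators and targets (from [cluster_features()]).
#' @param reg_gene Optional named vector site_id -> gene_id used to exclude
#'   self-gene regulators (taken from `reg$meta` when available).
#' @param n_trees,mtry,min_node Tree-ensemble parameters; `mtry` defaults
#'   to the square root of the number of candidates.
#' @param seed RNG seed.
#' @return data.frame of edges: `regulator`, `target`, `weight` (>= 0).
#' @export
infer_edges <- function(reg, targets, clusters = NULL, reg_gene = NULL,
                        n_trees = 500, mtry = NULL, min_node = 5,
                        seed = 1L) {
  if (inherits(reg, "RegulatorMatrix")) {
    if (is.null(reg_gene))
      reg_gene <- stats::setNames(reg$meta$gene_id, reg$meta$site_id)
    reg <- reg$values
  }
  if (!identical(colnames(reg), colnames(targets)))
    stop("regulator and target matrices must share sample columns")
  regs <- rownames(reg)
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- rownames(targets)[i]
    y <- targets[i, ]
    if (stats::sd(y) == 0) next  # zero-variance target: skipped
    cand <- regs
    if (!is.null(clusters) && tg %in% names(clusters)) {
      same <- regs[!is.na(clusters[regs]) & clusters[regs] == clusters[tg]]
      if (length(same)) cand <- same
    }
    if (!is.null(reg_gene))
      cand <- cand[is.na(reg_gene[cand]) | reg_gene[cand] != tg]
    if (!length(cand)) next
    X <- t(reg[cand, , drop = FALSE])
    ys <- (y - mean(y)) / stats::sd(y)
    k <- if (is.null(mtry)) max(1L, floor(sqrt(length(cand)))) else mtry
    imp <- .et_importance(X, ys, as.integer(n_trees), as.integer(k),
                          as.integer(min_node),
                          derive_seed(seed, 29L + i))
    out[[i]] <- data.frame(regulator = cand, target = tg,
                           weight = pmax(imp, 0),
                           stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(regulator = character(), target = character(),
                        weight = numeric())
  rownames(edges) <- NULL
  edges
}

#' Trim an inferred network by permutation
#'
#' Re-runs edge inference `n_perm` times with the regulator sample columns
#' shuffled relative to the targets, pools the null edge weights, assigns
#' each observed edge a smoothed permutation p-value
#' `(1 + #null >= w) / (1 + pool size)`, BH-adjusts, and retains edges with
#' adjusted p < `fdr` AND weight > `weight_floor`.
#'
#' @param reg,targets,clusters,reg_gene,n_trees,mtry,min_node,seed As in
#'   [infer_edges()].
#' @param n_perm Number of permutations (100).
#' @param weight_floor Conservative edge-weight cutoff (0.1).
#' @param fdr FDR level (0.05).
#' @return List: `edges` (retained, with `p`, `adj_p`), `all` (all scored
#'   edges), `null_size`.
#' @export
permutation_trim <- function(reg, targets, clusters = NULL, reg_gene = NULL,
                             n_perm = 100, weight_floor = 0.1, fdr = 0.05,
                             n_trees = 500, mtry = NULL, min_node = 5,
                             seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(reg, "RegulatorMatrix")) {
    if (is.null(reg_gene))
      reg_gene <- stats::setNames(reg$meta$gene_id, reg$meta$site_id)
    reg <- reg$values
  }
  obs <- infer_edges(reg, targets, clusters, reg_gene, n_trees, mtry,
                     min_node, seed)
  null_w <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, 101L + b),
                      sample.int(ncol(reg)))
    regp <- reg[, perm, drop = FALSE]
    colnames(regp) <- colnames(targets)
    ne <- infer_edges(regp, targets, clusters, reg_gene, n_trees, mtry,
                      min_node, derive_seed(seed, 201L + b))
    null_w[[b]] <- ne$weight
  }
  pool <- sort(unlist(null_w))
  np <- length(pool)
  ## #null >= w via binary search on the sorted pool
  ge <- np - findInterval(obs$weight - 1e-12, pool)
  obs$p <- (1 + ge) / (1 + np)
  obs$adj_p <- stats::p.adjust(obs$p, method = "BH")
  keep <- obs$adj_p < fdr & obs$weight > weight_floor
  list(edges = obs[keep, , drop = FALSE], all = obs, null_size = np)
}

#' Simplified cis-regulatory circuit linking
#'
#' Candidate (TF, peak, gene) triplets require a differential peak
#' (uncorrected p < `peak_p`), a differential gene (adjusted p <
#' `gene_adj_p`), a peak center within `window` bp of the gene's TSS and
#' the TF's motif in the peak. The linking statistic is the product of the
#' peak-gene sample correlation and the TF-activity-proxy-peak
#' correlation; significance comes from a sample-permutation null
#' (`n_perm` label shuffles of the RNA side) with BH adjustment. This is a
#' deliberately simplified, correlation-based stand-in for a full Bayesian
#' circuit sampler.
#'
#' @param atac_results,rna_results Tidy contrast tables for peaks / genes.
#' @param atac_mat,rna_mat Normalized value matrices (features x samples)
#'   sharing sample columns.
#' @param peak_meta data.frame: `peak_id`, `start`, `end`.
#' @param gene_tss Named numeric vector gene_id -> TSS position (genes
#'   without a TSS are skipped).
#' @param motif Binary peak x TF occupancy matrix.
#' @param tf_activity TF x samples activity-proxy matrix (TF transcript
#'   values by default).
#' @param window TSS window in bp (1e5).
#' @param peak_p,gene_adj_p Candidate thresholds (0.005 raw / 0.05
#'   adjusted).
#' @param n_perm Permutations for the null (1000).
#' @param fdr FDR level for retained circuits (0.05).
#' @param seed RNG seed.
#' @return List: `circuits` (retained: `tf`, `peak_id`, `gene_id`,
#'   `tss_distance`, `stat`, `p`, `adj_p`), `edges` (TF -> gene edges with
#'   provenance `"circuit-linking"`), `candidates` (all scored).
#' @export
infer_circuits <- function(atac_results, rna_results, atac_mat, rna_mat,
                           peak_meta, gene_tss, motif, tf_activity,
                           window = 1e5, peak_p = 0.005, gene_adj_p = 0.05,
                           n_perm = 1000, fdr = 0.05, seed = 1L) {
  shared <- intersect(colnames(atac_mat), colnames(rna_mat))
  n <- length(shared)
  da_peaks <- unique(atac_results$feature_id[atac_results$p < peak_p])
  da_genes <- unique(rna_results$feature_id[rna_results$adj_p < gene_adj_p])
  da_genes_tss <- da_genes[da_genes %in% names(gene_tss)]
  da_peaks <- intersect(da_peaks, peak_meta$peak_id)
  pm <- peak_meta[match(da_peaks, peak_meta$peak_id), , drop = FALSE]
  center <- (pm$start + pm$end) / 2
  cand <- NULL
  tfs <- colnames(motif)
  for (i in seq_along(da_peaks)) {
    near <- da_genes_tss[abs(gene_tss[da_genes_tss] - center[i]) <= window]
    if (!length(near)) next
    ptfs <- tfs[motif[da_peaks[i], ] > 0]
    ptfs <- intersect(ptfs, rownames(tf_activity))
    if (!length(ptfs)) next
    cand <- rbind(cand, expand.grid(tf = ptfs, peak_id = da_peaks[i],
                                    gene_id = near,
                                    stringsAsFactors = FALSE))
  }
  empty <- list(circuits = data.frame(), edges = data.frame(),
                candidates = data.frame())
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  cand$tss_distance <- (pm$start + pm$end)[match(cand$peak_id,
                                                 da_peaks)] / 2 -
    gene_tss[cand$gene_id]
  zrow <- function(x) {
    z <- (x - mean(x)) / stats::sd(x)
    z[!is.finite(z)] <- 0
    z
  }
  Zp <- t(apply(atac_mat[cand$peak_id, shared, drop = FALSE], 1, zrow))
  Zg <- t(apply(rna_mat[cand$gene_id, shared, drop = FALSE], 1, zrow))
  Zt <- t(apply(tf_activity[cand$tf, shared, drop = FALSE], 1, zrow))
  corfac <- 1 / (n - 1)
  stat_of <- function(Zg_, Zt_)
    (rowSums(Zp * Zg_) * corfac) * (rowSums(Zp * Zt_) * corfac)
  obs <- stat_of(Zg, Zt)
  exceed <- integer(nrow(cand))
  with_seed(derive_seed(seed, 303L), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      s <- stat_of(Zg[, perm, drop = FALSE], Zt[, perm, drop = FALSE])
      exceed <- exceed + (abs(s) >= abs(obs))
    }
  })
  cand$stat <- obs
  cand$p <- (1 + exceed) / (1 + n_perm)
  cand$adj_p <- stats::p.adjust(cand$p, method = "BH")
  keep <- cand$adj_p < fdr
  circuits <- cand[keep, , drop = FALSE]
  edges <- data.frame(regulator = circuits$tf, target = circuits$gene_id,
                      weight = abs(circuits$stat), modality = "circuit",
                      p = circuits$p, adj_p = circuits$adj_p,
                      provenance = "circuit-linking",
                      stringsAsFactors = FALSE)
  list(circuits = circuits, edges = edges, candidates = cand)
}

#' Union of inferred networks
#'
#' Multiset union: every record of every input network is retained, so an
#' edge predicted by two methods appears twice with its own modality and
#' provenance.
#'
#' @param ... Edge data.frames with at least `regulator`, `target`,
#'   `weight`; `modality` and `provenance` are filled when absent.
#' @return Combined edge data.frame.
#' @export
integrate_networks <- function(...) {
  nets <- list(...)
  cols <- c("regulator", "target", "weight", "modality", "p", "adj_p",
            "provenance")
  nets <- lapply(nets, function(e) {
    if (is.null(e) || nrow(e) == 0) return(NULL)
    for (cl in setdiff(cols, names(e)))
      e[[cl]] <- if (cl %in% c("modality", "provenance")) NA_character_
                 else NA_real_
    if (all(is.na(e$provenance))) e$provenance <- "edge-inference"
    e[, cols]
  })
  out <- do.call(rbind, nets)
  if (is.null(out))
    out <- stats::setNames(
      data.frame(character(), character(), numeric(), character(),
                 numeric(), numeric(), character()), cols)
  rownames(out) <- NULL
  out
}

#' Count directed network motifs per node
#'
#' Exhaustive per-node instance counts for the feed-forward loop
#' (A->B, A->C, B->C), the 3-chain (A->B->C, distinct nodes) and the
#' diamond (A->B, A->C, B->D, C->D, distinct nodes), computed with
#' adjacency-matrix algebra on the simple graph (parallel records
#' collapsed). Self-loops are rejected.
#'
#' @param edges Edge data.frame (`regulator`, `target`) or an igraph.
#' @return data.frame: `node`, `ffl`, `chain3`, `diamond` (nonnegative
#'   integers).
#' @export
count_motifs <- function(edges) {
  if (inherits(edges, "igraph")) {
    el <- igraph::as_data_frame(edges)
    edges <- data.frame(regulator = el[[1]], target = el[[2]],
                        stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0)
    return(data.frame(node = character(), ffl = integer(),
                      chain3 = integer(), diamond = integer()))
  if (any(edges$regulator == edges$target))
    stop("self-loops are not allowed in motif counting")
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  nN <- length(nodes)
  A <- matrix(0, nN, nN, dimnames = list(nodes, nodes))
  A[cbind(match(edges$regulator, nodes), match(edges$target, nodes))] <- 1
  P2 <- A %*% A
  AAt <- A %*% t(A)
  AtA <- t(A) %*% A
  recip <- diag(P2)
  indeg <- colSums(A); outdeg <- rowSums(A)

  ffl <- rowSums(P2 * A) +              # source role
    rowSums(t(A) * AAt) +               # middle role
    colSums(A * AtA)                    # sink role

  chain3 <- (rowSums(P2) - diag(P2)) +  # source
    (indeg * outdeg - recip) +          # middle
    (colSums(P2) - diag(P2))            # sink

  Q <- P2; diag(Q) <- 0
  ch2 <- Q * (Q - 1) / 2
  side <- diag(t(A) %*% Q %*% t(A)) - (indeg * outdeg - recip)
  diamond <- rowSums(ch2) + colSums(ch2) + side

  data.frame(node = nodes, ffl = as.integer(round(ffl)),
             chain3 = as.integer(round(chain3)),
             diamond = as.integer(round(diamond)),
             stringsAsFactors = FALSE)
}

#' Network Motif Score
#'
#' Per node, the sum over motif types of the min-max-normalized instance
#' count; a motif type with constant counts across nodes contributes 0.
#' NMS therefore lies between 0 and the number of motif types.
#'
#' @param counts Output of [count_motifs()].
#' @return The input with an `nms` column appended.
#' @export
network_motif_score <- function(counts) {
  if (nrow(counts) == 0) {
    counts$nms <- numeric(0)
    return(counts)
  }
  norm01 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  counts$nms <- norm01(counts$ffl) + norm01(counts$chain3) +
    norm01(counts$diamond)
  counts
}
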