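## Independent oracles used across the suite. These deliberately re-derive
## each statistic from its definition (brute force / closed form) and never
## call the package code paths they check.

## TMM factor for one sample against a reference, straight from the
## definition: doubly trimmed, precision-weighted mean of M-values
brute_tmm_one <- function(y, yr, libj, libr, mtrim = 0.3, atrim = 0.05) {
  ok <- y > 0 & yr > 0
  M <- log2((y[ok] / libj) / (yr[ok] / libr))
  A <- 0.5 * log2((y[ok] / libj) * (yr[ok] / libr))
  v <- (libj - y[ok]) / (libj * y[ok]) + (libr - yr[ok]) / (libr * yr[ok])
  n <- length(M)
  keepM <- rank(M) >= floor(n * mtrim) + 1 & rank(M) <= n - floor(n * mtrim)
  keepA <- rank(A) >= floor(n * atrim) + 1 & rank(A) <= n - floor(n * atrim)
  keep <- keepM & keepA
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

## running-sum area enrichment score, re-derived step by step
brute_es <- function(stats_named, members) {
  ord <- order(stats_named, decreasing = TRUE)
  is_m <- names(stats_named)[ord] %in% members
  m <- sum(is_m); N <- length(stats_named)
  run <- 0; acc <- 0
  for (i in seq_len(N)) {
    run <- run + if (is_m[i]) 1 / m else -1 / (N - m)
    acc <- acc + run
  }
  acc / N
}

## exhaustive per-node motif counts over all node triples / quadruples
brute_motifs <- function(edges) {
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  has <- function(a, b) any(edges$regulator == a & edges$target == b)
  ffl <- chain3 <- diamond <- stats::setNames(integer(length(nodes)), nodes)
  for (a in nodes) for (b in nodes) for (c in nodes) {
    if (length(unique(c(a, b, c))) < 3) next
    if (has(a, b) && has(a, c) && has(b, c)) {
      ffl[a] <- ffl[a] + 1; ffl[b] <- ffl[b] + 1; ffl[c] <- ffl[c] + 1
    }
    if (has(a, b) && has(b, c)) {
      chain3[a] <- chain3[a] + 1; chain3[b] <- chain3[b] + 1
      chain3[c] <- chain3[c] + 1
    }
  }
  for (a in nodes) for (b in nodes) for (c in nodes) for (d in nodes) {
    if (length(unique(c(a, b, c, d))) < 4) next
    if (b < c && has(a, b) && has(a, c) && has(b, d) && has(c, d)) {
      diamond[a] <- diamond[a] + 1; diamond[b] <- diamond[b] + 1
      diamond[c] <- diamond[c] + 1; diamond[d] <- diamond[d] + 1
    }
  }
  data.frame(node = nodes, ffl = as.integer(ffl),
             chain3 = as.integer(chain3), diamond = as.integer(diamond),
             stringsAsFactors = FALSE)
}

## dense-matrix REML criterion for y = X b + Z u + e, evaluated directly
brute_reml_crit <- function(lambda, y, Xmat, pid) {
  Z <- stats::model.matrix(~ 0 + factor(pid))
  V <- diag(length(y)) + lambda * Z %*% t(Z)
  Vi <- solve(V)
  A <- t(Xmat) %*% Vi %*% Xmat
  beta <- solve(A, t(Xmat) %*% Vi %*% y)
  r <- y - Xmat %*% beta
  df <- length(y) - ncol(Xmat)
  s2 <- as.numeric(t(r) %*% Vi %*% r) / df
  as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(A)$modulus) + df * log(s2)
}

## rank-based AUROC of scores for a binary truth labelling
auroc <- function(score, label) {
  r <- rank(score)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}

## small shared synthetic bundle, built once per test run
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(group_counts = c(CON = 10, EE = 12, RE = 12),
                           n_genes = 60, n_tfs = 6, n_peaks = 80,
                           n_phosphosites = 60, n_metabolites = 30,
                           n_pathways = 10,
                           n_perturbed = list(rna = 5, atac = 5, protein = 3,
                                              phospho = 5, metab = 3),
                           seed = 7)
      cache <<- simulate_bundle(cfg)
    }
    cache
  }
})
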