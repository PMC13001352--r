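test_that("regulator preparation filters, imputes and averages", {
  b <- small_bundle()
  ph <- normalize_omics(b$omics$phospho)
  reg <- prepare_regulators(ph, b$truth$tf_genes)
  expect_false(anyNA(reg$values))
  expect_true(all(reg$meta$gene_id %in% b$truth$tf_genes))

  ## a site with 45% missing is dropped, <= 40% kept
  x <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("TF1_S1", "TF1_S2"), paste0("s", 1:20)))
  x["TF1_S1", 1:9] <- NA   # 45%
  x["TF1_S2", 1:8] <- NA   # 40%
  m <- omics_matrix(x, "phospho",
                    data.frame(site_id = rownames(x),
                               gene_id = c("TF1", "TF1")))
  ## a second complete site so imputation has a predictor
  reg2 <- prepare_regulators(m, "TF1")
  expect_false("TF1_S1" %in% rownames(reg2$values))
  expect_true("TF1_S2" %in% rownames(reg2$values))

  ## no missing values -> output equals input
  xc <- matrix(rnorm(60), 3, 20,
               dimnames = list(paste0("TF1_S", 1:3), paste0("s", 1:20)))
  mc <- omics_matrix(xc, "phospho",
                     data.frame(site_id = rownames(xc), gene_id = "TF1"))
  expect_identical(prepare_regulators(mc, "TF1")$values, xc)
  expect_error(prepare_regulators(mc, character(0)), "nonempty")
})

test_that("chained-equations imputation beats column-mean on MCAR data", {
  set.seed(31)
  shared <- rnorm(40)
  base <- outer(rnorm(25), shared) + matrix(rnorm(25 * 40, 0, 0.3), 25)
  dimnames(base) <- list(paste0("f", 1:25), paste0("s", 1:40))
  masked <- base
  holes <- cbind(sample(1:25, 60, TRUE), sample(1:40, 60, TRUE))
  holes <- holes[!duplicated(holes), ]
  masked[holes] <- NA
  acc <- 0
  for (s in 1:15) acc <- acc + mice_impute(masked, seed = s)
  mi <- acc / 15
  rowmean <- masked
  for (f in 1:25) rowmean[f, is.na(rowmean[f, ])] <-
    mean(rowmean[f, ], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[holes] - base[holes])^2))
  expect_lt(rmse(mi), rmse(rowmean))
})

test_that("fuzzifier and fuzzy c-means behave as specified", {
  ## direct evaluation of the estimator formula at N = 100, D = 8
  N <- 100; D <- 8
  m_ref <- 1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  expect_equal(estimate_fuzzifier(100, 8), m_ref, tolerance = 1e-12)

  ## two well-separated profile shapes: near-crisp memberships at c = 2
  set.seed(32)
  up <- c(5, 5, 5, -5, -5, -5)
  x <- rbind(matrix(rep(up, each = 40), 40) + rnorm(240, 0, 0.2),
             matrix(rep(-up, each = 40), 40) + rnorm(240, 0, 0.2))
  rownames(x) <- paste0("f", 1:80)
  cl <- cluster_features(x, c_range = 2:4)
  expect_equal(rowSums(cl$membership), rep(1, 80), tolerance = 1e-9)
  own <- apply(cl$membership, 1, max)
  expect_gt(mean(own > 0.95), 0.9)
  ## the two planted blobs never co-cluster
  expect_true(all(cl$cluster[1:40] != cl$cluster[41:80]))
  expect_error(cluster_features(x, c_range = 1:3), "c_range")
})

test_that("tree-ensemble importances find a planted linear regulator", {
  ## y = 2 x1 + noise among 5 candidates: top importance in >= 95/100 runs
  set.seed(33)
  n <- 40
  hits <- 0
  for (run in 1:100) {
    R <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("TFs_S", 1:5), paste0("s", 1:n)))
    y <- 2 * R[1, ] + rnorm(n, 0, 0.3)
    tgt <- matrix(y, 1, dimnames = list("gene1", colnames(R)))
    ed <- infer_edges(R, tgt, n_trees = 100, seed = run)
    hits <- hits + (ed$regulator[which.max(ed$weight)] == "TFs_S1")
  }
  expect_gte(hits, 95)

  ## importances nonnegative and finite
  R <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("TFs_S", 1:5), paste0("s", 1:n)))
  tgt <- matrix(rnorm(2 * n), 2,
                dimnames = list(c("g1", "g2"), colnames(R)))
  ed <- infer_edges(R, tgt, n_trees = 50, seed = 1)
  expect_true(all(is.finite(ed$weight)) && all(ed$weight >= 0))

  ## independent target: max importance far below planted-signal level
  set.seed(34)
  null_max <- sig_min <- numeric(20)
  for (i in 1:20) {
    R <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("TFs_S", 1:5), paste0("s", 1:n)))
    y_sig <- 2 * R[1, ] + rnorm(n, 0, 0.3)
    y_null <- rnorm(n)
    tg <- rbind(gsig = y_sig, gnull = y_null)
    colnames(tg) <- colnames(R)
    ed <- infer_edges(R, tg, n_trees = 100, seed = i)
    null_max[i] <- max(ed$weight[ed$target == "gnull"])
    sig_min[i] <- max(ed$weight[ed$target == "gsig"])
  }
  expect_lt(max(null_max), quantile(sig_min, 0.05))

  ## cluster restriction: co-clustered regulators are the candidate set
  cl <- c(TFs_S1 = 1, TFs_S2 = 1, TFs_S3 = 2, TFs_S4 = 2, TFs_S5 = 2,
          g1 = 1)
  tgt1 <- matrix(rnorm(n), 1, dimnames = list("g1", colnames(R)))
  edc <- infer_edges(R, tgt1, clusters = cl, n_trees = 20, seed = 1)
  expect_setequal(edc$regulator, c("TFs_S1", "TFs_S2"))

  ## a regulator on the target's own gene is excluded
  edx <- infer_edges(R, tgt1,
                     reg_gene = stats::setNames(
                       c("g1", "TF", "TF", "TF", "TF"), rownames(R)),
                     n_trees = 20, seed = 1)
  expect_false("TFs_S1" %in% edx$regulator)
})

test_that("permutation trimming enforces its defaults and calibration", {
  expect_equal(eval(formals(permutation_trim)$n_perm), 100)
  expect_equal(eval(formals(permutation_trim)$weight_floor), 0.1)
  set.seed(35)
  n <- 30
  R <- matrix(rnorm(8 * n), 8, n,
              dimnames = list(paste0("TFx_S", 1:8), paste0("s", 1:n)))
  tgt <- matrix(rnorm(15 * n), 15,
                dimnames = list(paste0("g", 1:15), colnames(R)))
  tr <- permutation_trim(R, tgt, n_perm = 30, n_trees = 50, seed = 2)
  ## every retained edge satisfies both cutoffs
  expect_true(all(tr$edges$weight > 0.1))
  expect_true(all(tr$edges$adj_p < 0.05))
  ## p-values in (0, 1]: the smoothed estimator never returns 0
  expect_true(all(tr$all$p > 0 & tr$all$p <= 1))
  ## fully null data passes (almost) nothing at FDR 0.05
  expect_lt(nrow(tr$edges) / nrow(tr$all), 0.05 + 2 * sqrt(0.05 / nrow(tr$all)))
  expect_error(permutation_trim(R, tgt, n_perm = 0), "n_perm")
})

test_that("network integration is a multiset union with provenance", {
  e1 <- data.frame(regulator = "TF_S1", target = "g1", weight = 0.5,
                   modality = "EE", provenance = "edge-inference")
  e2 <- data.frame(regulator = "TF_S1", target = "g1", weight = 0.2,
                   modality = "circuit", provenance = "circuit-linking")
  both <- integrate_networks(e1, e2)
  expect_equal(nrow(both), 2)                 # same edge reported twice
  expect_setequal(both$provenance, c("edge-inference", "circuit-linking"))
  ## disjoint inputs: sizes add; order-invariant up to record order
  e3 <- data.frame(regulator = "TF_S2", target = "g2", weight = 1)
  ab <- integrate_networks(e1, e3)
  ba <- integrate_networks(e3, e1)
  expect_equal(nrow(ab), 2)
  expect_setequal(paste(ab$regulator, ab$target),
                  paste(ba$regulator, ba$target))
})

test_that("circuit linking respects its candidate thresholds", {
  ## construct two peaks: one inside the window with a motif, one outside
  set.seed(36)
  n <- 40
  samples <- paste0("s", 1:n)
  tfsig <- rnorm(n)
  peak_in <- 0.9 * tfsig + rnorm(n, 0, 0.3)
  gene_sig <- 0.9 * peak_in + rnorm(n, 0, 0.3)
  atac_mat <- rbind(peakA = peak_in, peakB = rnorm(n), peakC = peak_in)
  colnames(atac_mat) <- samples
  rna_mat <- rbind(gene1 = gene_sig, gene2 = rnorm(n))
  colnames(rna_mat) <- samples
  tfa <- matrix(tfsig, 1, dimnames = list("TF1", samples))
  peak_meta <- data.frame(peak_id = c("peakA", "peakB", "peakC"),
                          start = c(1000, 500000, 1000),
                          end = c(1200, 500200, 1200))
  gene_tss <- c(gene1 = 2000, gene2 = 160000)
  motif <- matrix(c(1, 1, 0), 3, 1,
                  dimnames = list(peak_meta$peak_id, "TF1"))
  atac_res <- data.frame(feature_id = c("peakA", "peakB", "peakC"),
                         p = c(0.001, 0.001, 0.01))   # peakC fails raw p
  rna_res <- data.frame(feature_id = c("gene1", "gene2"),
                        adj_p = c(0.01, 0.01))
  cc <- infer_circuits(atac_res, rna_res, atac_mat, rna_mat, peak_meta,
                       gene_tss, motif, tfa, n_perm = 200, seed = 3)
  cand_peaks <- unique(cc$candidates$peak_id)
  expect_false("peakB" %in% cand_peaks)   # 498 kb from any TSS
  expect_false("peakC" %in% cand_peaks)   # raw p = 0.01 >= 0.005
  expect_true("peakA" %in% cand_peaks)
  ## the planted TF -> peakA -> gene1 circuit is recovered
  expect_true(any(cc$circuits$peak_id == "peakA" &
                    cc$circuits$gene_id == "gene1"))
  expect_true(all(cc$edges$provenance == "circuit-linking"))
})

test_that("motif counts equal brute-force enumeration", {
  ## triangle cycle: no FFL, each node in exactly 3 three-chains
  tri <- data.frame(regulator = c("A", "B", "C"), target = c("B", "C", "A"))
  ct <- count_motifs(tri)
  expect_equal(ct$ffl, c(0L, 0L, 0L))
  expect_equal(ct$chain3, c(3L, 3L, 3L))
  ## minimal FFL: exactly one instance, A participates once
  ffl <- data.frame(regulator = c("A", "A", "B"), target = c("B", "C", "C"))
  cf <- count_motifs(ffl)
  expect_equal(cf$ffl[cf$node == "A"], 1L)
  ## random 8-node digraphs vs brute force over 20 seeds
  for (s in 1:20) {
    set.seed(s)
    nodes <- LETTERS[1:8]
    all_pairs <- expand.grid(regulator = nodes, target = nodes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$regulator != all_pairs$target, ]
    edges <- all_pairs[runif(nrow(all_pairs)) < 0.25, ]
    if (nrow(edges) == 0) next
    got <- count_motifs(edges)
    want <- brute_motifs(edges)
    expect_equal(got, want, info = paste("seed", s))
  }
  expect_error(count_motifs(data.frame(regulator = "A", target = "A")),
               "self-loop")
})

test_that("the network motif score normalizes and ranks invariantly", {
  edges <- data.frame(regulator = c("A", "A", "B", "C", "D"),
                      target = c("B", "C", "C", "D", "E"))
  nm <- network_motif_score(count_motifs(edges))
  expect_true(all(nm$nms >= 0 & nm$nms <= 3))
  ## node E participates in chains only via D -> E
  ## an isolated-in-motifs node scores 0
  iso_edges <- rbind(edges, data.frame(regulator = "X", target = "Y"))
  nmi <- network_motif_score(count_motifs(iso_edges))
  expect_equal(nmi$nms[nmi$node == "Y"], 0)
  ## a node attaining the maximum count of every type scores 3
  hub <- data.frame(
    regulator = c("A", "A", "B", "A", "D", "A", "A", "F", "G"),
    target    = c("B", "C", "C", "D", "E", "F", "G", "H", "H"))
  nmh <- network_motif_score(count_motifs(hub))
  cmax <- apply(nmh[c("ffl", "chain3", "diamond")], 2, max)
  arow <- nmh[nmh$node == "A", ]
  expect_equal(unlist(arow[c("ffl", "chain3", "diamond")]),
               cmax, ignore_attr = TRUE)
  expect_equal(arow$nms, 3)
  ## relabeling invariance of the ranking
  perm <- c(A = "Q", B = "R", C = "S", D = "T", E = "U")
  edges2 <- data.frame(regulator = perm[edges$regulator],
                       target = perm[edges$target])
  nm2 <- network_motif_score(count_motifs(edges2))
  expect_equal(nm$nms[order(nm$node)],
               nm2$nms[order(names(perm)[match(nm2$node, perm)])])
})
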