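test_that("z transform and z-matrix collapse follow the stated rules", {
  expect_equal(t_to_z(0, 10), 0)                       # median -> median
  expect_equal(t_to_z(c(-2, 2), 30), -rev(t_to_z(c(-2, 2), 30)))
  expect_true(all(is.finite(t_to_z(c(-50, 50), 5))))   # deep-tail stability

  res <- data.frame(
    feature_id = c("tx1", "tx2", "f3"),
    contrast = "EE_15min",
    t = c(3.1, -1.2, 0.5), df_total = c(20, 20, 20),
    stringsAsFactors = FALSE)
  map <- c(tx1 = "GENEA", tx2 = "GENEA", f3 = "GENEB")
  z <- build_zscore_matrix(res, map)
  ## most extreme |z| retained for the multi-feature gene
  expect_equal(z["GENEA", "EE_15min"], t_to_z(3.1, 20))
  expect_equal(z["GENEB", "EE_15min"], t_to_z(0.5, 20))  # identity mapping
  ## unmapped features dropped with a count
  res2 <- rbind(res, data.frame(feature_id = "orphan", contrast = "EE_15min",
                                t = 1, df_total = 20))
  z2 <- build_zscore_matrix(res2, map)
  expect_equal(attr(z2, "n_unmapped"), 1L)
})

test_that("multi-site phosphosites split with max-|z| deduplication", {
  tab <- data.frame(site_id = c("PROT_S1;S2", "PROT_S1", "OTHER_T7"),
                    z = c(1.2, 0.5, -0.3), stringsAsFactors = FALSE)
  out <- split_multisite(tab)
  ## PROT_S1;S2 expands; duplicated PROT_S1 resolved to max |z| (1.2)
  expect_setequal(out$site_id, c("PROT_S1", "PROT_S2", "OTHER_T7"))
  expect_equal(out$z[out$site_id == "PROT_S1"], 1.2)
  expect_equal(out$z[out$site_id == "PROT_S2"], 1.2)
  ## negative extreme wins on magnitude
  tab2 <- data.frame(site_id = c("P_S1", "P_S1"), z = c(0.5, -0.9))
  expect_equal(split_multisite(tab2)$z, -0.9)
  ## already-single table unchanged (up to ordering)
  tab3 <- data.frame(site_id = c("A_S1", "B_Y2"), z = c(1, 2))
  expect_setequal(split_multisite(tab3)$site_id, tab3$site_id)
  expect_error(split_multisite(data.frame(site_id = "garbage", z = 1)),
               "unparseable")
})

test_that("set filtering enforces size and retention thresholds", {
  universe <- paste0("g", 1:100)
  sets <- list(
    drop_small = paste0("g", 1:4),              # < 5 survivors
    drop_retention = c(paste0("g", 1:6), paste0("x", 1:4)),  # 60% < 70%
    keep = paste0("g", 10:29))                  # fully covered
  out <- filter_sets(sets, universe)
  expect_named(out, "keep")
  expect_length(out$keep, 20)
  ## retention rule waived for non-gene collections
  out2 <- filter_sets(sets["drop_retention"], universe,
                      is_gene_sets = FALSE)
  expect_length(out2$drop_retention, 6)
  expect_error(filter_sets(sets, character(0)), "empty universe")
})

test_that("CAMERA-PR matches the two-sample t-test at rho = 0", {
  ## G = 6, m = 2: closed-form equal-variance two-sample t oracle
  z <- stats::setNames(c(1.2, -0.4, 0.3, 2.1, -1.0, 0.6), paste0("g", 1:6))
  set <- list(S = c("g1", "g4"))
  out <- camera_pr(z, set, rho = 0)
  in_set <- c(1.2, 2.1); out_set <- c(-0.4, 0.3, -1.0, 0.6)
  sp <- sqrt(((2 - 1) * var(in_set) + (4 - 1) * var(out_set)) / (6 - 2))
  t_ref <- (mean(in_set) - mean(out_set)) / (sp * sqrt(1 / 2 + 1 / 4))
  expect_equal(out$statistic, t_ref, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(-abs(t_ref), 4), tolerance = 1e-10)

  ## all z equal -> statistic 0, p = 1
  zc <- stats::setNames(rep(1.5, 10), paste0("g", 1:10))
  outc <- camera_pr(zc, list(S = paste0("g", 1:3)))
  expect_equal(outc$statistic, 0)
  expect_equal(outc$p, 1)
  ## kinase threshold 0.10
  expect_true(camera_pr(z, set, alpha = 0.10)$significant ==
                (camera_pr(z, set, alpha = 0.10)$adj_p < 0.10))
  ## set = universe undefined -> NA
  expect_true(is.na(camera_pr(z, list(S = paste0("g", 1:6)))$p))
})

test_that("CAMERA-PR p-values are uniform under the null at rho = 0", {
  set.seed(13)
  ps <- vapply(1:1000, function(i) {
    z <- stats::setNames(rnorm(40), paste0("g", 1:40))
    camera_pr(z, list(S = sample(names(z), 8)), rho = 0)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ORA equals exact hypergeometric enumeration", {
  universe <- paste0("u", 1:20)
  sets <- list(S = paste0("u", 1:5))
  hits <- paste0("u", 1:5)
  out <- ora(hits, universe, sets)
  ## overlap 5 of 5 drawn from 20: p = 1 / C(20,5) by direct enumeration
  expect_equal(out$p, 1 / choose(20, 5), tolerance = 1e-12)
  ## hits = universe -> saturation, p = 1 for every set
  outs <- ora(universe, universe, sets)
  expect_equal(outs$p, 1)
  ## overlap 0: p bounded by 1 minus the hypergeometric mass at 0
  out0 <- ora(paste0("u", 6:10), universe, sets)
  expect_gte(out0$p, 1 - dhyper(0, 5, 15, 5))
  expect_error(ora(hits, character(0), sets), "empty universe")
  ## monotone: larger overlap at fixed margins never raises p
  p_at <- vapply(3:5, function(k)
    ora(c(paste0("u", 1:k), paste0("u", 10:(14 - k))), universe, sets)$p,
    numeric(1))
  expect_true(all(diff(p_at) <= 1e-12))
})

test_that("PTM-SEA running-sum score matches a brute-force oracle", {
  set.seed(3)
  z <- stats::setNames(rnorm(10), paste0("P", 1:10, "_S1"))
  members <- paste0("P", c(2, 5, 7, 8, 9), "_S1")
  sig <- list(SIG = paste0(members, ";u"))
  out <- ptm_sea(z, sig, nperm = 50, min_overlap = 5, seed = 2)
  expect_equal(out$es, brute_es(z, members), tolerance = 1e-12)

  ## members at the very top of a 100-feature list: ES maximal over random
  ## placements of the same number of members
  z100 <- stats::setNames(sort(rnorm(100), decreasing = TRUE),
                          paste0("Q", 1:100, "_S1"))
  top <- names(z100)[1:8]
  es_top <- ptm_sea(z100, list(S = paste0(top, ";u")), nperm = 10,
                    seed = 1)$es
  expect_gt(es_top, 0)
  set.seed(4)
  for (i in 1:50) {
    rnd <- sample(names(z100), 8)
    expect_lte(brute_es(z100, rnd), es_top + 1e-12)
  }

  ## 4-member signature skipped (min.overlap = 5)
  out4 <- ptm_sea(z, list(S = paste0(paste0("P", 1:4, "_S1"), ";u")),
                  nperm = 10)
  expect_equal(nrow(out4), 0L)
  expect_error(ptm_sea(z, sig, nperm = 0), "nperm")

  ## negating every statistic negates every ES
  out_pos <- ptm_sea(z, sig, nperm = 20, seed = 5)
  out_neg <- ptm_sea(-z, sig, nperm = 20, seed = 5)
  expect_equal(out_neg$es, -out_pos$es, tolerance = 1e-12)

  ## directional handling: "d"-tagged members are sign-flipped before the
  ## per-signature ranking
  sig_d <- list(SIG = paste0(members, ";d"))
  z_flip <- z
  z_flip[members] <- -z_flip[members]
  expect_equal(ptm_sea(z, sig_d, nperm = 10, seed = 1)$es,
               brute_es(z_flip, members), tolerance = 1e-12)
})

test_that("PTM-SEA permutation p is invariant to feature relabeling", {
  set.seed(6)
  z <- stats::setNames(rnorm(60), paste0("P", 1:60, "_S1"))
  members <- names(z)[1:10]
  p1 <- ptm_sea(z, list(S = members), nperm = 200, seed = 9)$p
  ## relabel all ids consistently
  names_new <- paste0("R", 1:60, "_S2")
  z2 <- stats::setNames(unname(z), names_new)
  members2 <- names_new[1:10]
  p2 <- ptm_sea(z2, list(S = members2), nperm = 200, seed = 9)$p
  expect_equal(p1, p2)
})

test_that("localization filter keeps sites above the confidence cut", {
  meta <- data.frame(site_id = c("a", "b", "c"),
                     confident_score = c(17, 17.01, 30))
  expect_equal(confident_sites(meta), c("b", "c"))
})
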