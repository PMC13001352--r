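## complete all-arm design for construction tests
mk_design <- function(n_per_group, seed = 1) {
  cohort <- cohort_config(
    group_counts = c(CON = n_per_group, EE = n_per_group,
                     RE = n_per_group),
    arm_probs = c(Early = 0, Middle = 0, Late = 0, All = 1), seed = seed)
  generate_cohort(cohort)
}

test_that("eligibility requires 3 paired participants everywhere", {
  d <- mk_design(4)
  x <- matrix(rnorm(2 * nrow(d)), 2,
              dimnames = list(c("full", "sparse"), d$sample_id))
  ## 'sparse': only 2 RE participants observed at 24h
  re24 <- d$sample_id[d$group == "RE" & d$timepoint == "24h"]
  x["sparse", re24[1:2]] <- NA
  elig <- eligibility_filter(d, omics_matrix(x, "protein"))
  expect_true(elig[["full"]])     # complete data -> eligible
  expect_false(elig[["sparse"]])
  ## a group with zero samples at a timepoint blocks everything
  d2 <- d[!(d$group == "CON" & d$timepoint == "24h"), ]
  elig2 <- eligibility_filter(d2, omics_matrix(
    x[, d2$sample_id, drop = FALSE], "protein"))
  expect_false(any(elig2))
})

test_that("cell-means fit matches OLS and a brute-force REML oracle", {
  ## balanced complete design, no covariates: cell means = cell averages
  d <- mk_design(6)
  set.seed(2)
  y <- stats::setNames(rnorm(nrow(d)), d$sample_id)
  fit <- fit_cell_means(y, d, covariates = character(0))
  avg <- tapply(y, paste(d$group, d$timepoint, sep = "."), mean)
  expect_equal(unname(fit$cells[names(avg)]), as.numeric(avg),
               tolerance = 1e-8)

  ## REML variance ratio vs dense-matrix profiled-likelihood grid search
  d6 <- mk_design(2)   # 6 participants
  set.seed(3)
  b <- rnorm(6, 0, 0.8)[match(d6$participant_id,
                              unique(d6$participant_id))]
  y6 <- stats::setNames(1 + b + rnorm(nrow(d6), 0, 0.5), d6$sample_id)
  fit6 <- fit_cell_means(y6, d6, covariates = character(0))
  X <- stats::model.matrix(~ 0 + factor(paste(d6$group, d6$timepoint)))
  grid <- exp(seq(log(1e-4), log(1e3), length.out = 400))
  crit <- vapply(grid, brute_reml_crit, numeric(1), y = unname(y6),
                 Xmat = X, pid = d6$participant_id)
  lam_grid <- grid[which.min(crit)]
  expect_equal(log(fit6$lambda + 1e-4), log(lam_grid + 1e-4),
               tolerance = 0.05)

  ## constant covariate -> skipped with a singularity code
  d$const <- "x"
  fit_bad <- fit_cell_means(y, d, covariates = "const")
  expect_true(fit_bad$skipped)
  expect_match(fit_bad$reason, "singular")
})

test_that("delta-delta contrasts obey their arithmetic identities", {
  d <- mk_design(4)
  ## construct data with exact cell means
  mu <- c(CON.pre = 1, CON.15min = 1, EE.pre = 1, EE.15min = 2)
  y <- stats::setNames(rep(0, nrow(d)), d$sample_id)
  cell <- paste(d$group, d$timepoint, sep = ".")
  y[] <- ifelse(cell %in% names(mu), mu[cell], 0)
  fit <- fit_cell_means(y, d, covariates = character(0))
  ct <- delta_delta_contrast(fit, "EE", "15min")
  expect_equal(ct$estimate, 1, tolerance = 1e-8)
  ## all four cells equal -> 0
  ct0 <- delta_delta_contrast(fit, "RE", "15min")
  expect_equal(ct0$estimate, -0, tolerance = 1e-8)
  ## missing cell named in the error
  d3 <- d[!(d$group == "EE" & d$timepoint == "24h"), ]
  fit3 <- fit_cell_means(y[d3$sample_id], d3, covariates = character(0))
  expect_error(delta_delta_contrast(fit3, "EE", "24h"), "EE.24h")

  ## antisymmetry under swapping exercise and control labels
  set.seed(4)
  yr <- stats::setNames(rnorm(nrow(d)), d$sample_id)
  f1 <- fit_cell_means(yr, d, covariates = character(0))
  dsw <- d
  dsw$group[d$group == "EE"] <- "CON"
  dsw$group[d$group == "CON"] <- "EE"
  f2 <- fit_cell_means(yr, dsw, covariates = character(0))
  e1 <- delta_delta_contrast(f1, "EE", "3.5h")$estimate
  e2 <- delta_delta_contrast(f2, "EE", "3.5h")$estimate
  expect_equal(e1, -e2, tolerance = 1e-8)
})

test_that("a simulated delta is recovered by the model on average", {
  ## generative-parameter recovery, scaled down from 500 to 60 replicates
  d <- mk_design(10)
  nr <- 60
  set.seed(6)
  ests <- vapply(seq_len(nr), function(i) {
    b <- rnorm(30, 0, 0.3)[match(d$participant_id,
                                 unique(d$participant_id))]
    y <- b + rnorm(nrow(d), 0, 0.5)
    shift <- d$group == "EE" & d$timepoint == "15min"
    y <- stats::setNames(y + 1.5 * shift, d$sample_id)
    fit <- fit_cell_means(y, d, covariates = character(0))
    delta_delta_contrast(fit, "EE", "15min")$estimate
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(nr)
  expect_lt(abs(mean(ests) - 1.5), 3 * mc_se)
})

test_that("variance moderation recovers a known prior and degenerates correctly", {
  ## equal variances -> posterior equals that value, moderated t = raw t
  sq <- squeeze_var(rep(2, 50), df = 10)
  expect_equal(sq$var_post, rep(2, 50), tolerance = 1e-6)

  ## variances from scaled inv-chi2(d0 = 4, s0^2 = 2), 5000 features
  set.seed(9)
  d0 <- 4; s02 <- 2; df <- 10
  sigma2 <- d0 * s02 / rchisq(5000, d0)
  s2 <- sigma2 * rchisq(5000, df) / df
  est <- squeeze_var(s2, df)
  expect_lt(abs(est$df_prior - d0) / d0, 0.20)
  ## cross-check the whole moderation against the reference implementation
  ref <- limma::squeezeVar(s2, df)
  expect_equal(est$var_post, ref$var.post, tolerance = 1e-6)
  ## single feature: warning, no shrinkage
  expect_warning(squeeze_var(3, 10), "no variance shrinkage")
})

test_that("moderated results table is well-formed and BH is per contrast", {
  b <- small_bundle()
  res <- differential_analysis(b$omics$rna, b$design)
  expect_true(all(res$adj_p >= res$p - 1e-12))
  expect_equal(abs(res$t), abs(res$estimate / res$se), tolerance = 1e-9)
  ## BH applied within (ome, contrast): recompute one stratum
  st <- res[res$group == "EE" & res$timepoint == "15min", ]
  expect_equal(st$adj_p, p.adjust(st$p, "BH"))
  ## BH invariant to input order
  perm <- sample(nrow(res))
  res2 <- moderate_and_adjust(res[perm, c("feature_id", "ome", "group",
                                          "timepoint", "estimate",
                                          "se_unscaled", "s2", "df",
                                          "n_used")])
  key <- function(r) paste(r$feature_id, r$group, r$timepoint)
  expect_equal(res2$adj_p[match(key(res), key(res2))], res$adj_p,
               tolerance = 1e-12)
})

test_that("voom-style weights follow the mean-variance trend", {
  ## NB counts over a wide abundance range: the log-scale variance trend
  ## 1/mu + phi falls with abundance, so weights must rise with it
  d <- mk_design(4)
  set.seed(11)
  mu <- 2^runif(500, 2, 10)
  counts <- matrix(rnbinom(500 * nrow(d), mu = rep(mu, nrow(d)),
                           size = 1 / 0.2),
                   nrow = 500,
                   dimnames = list(paste0("g", 1:500), d$sample_id))
  vw <- voom_weights(counts, d, covariates = character(0))
  expect_true(all(vw$weights > 0))
  wbar <- rowMeans(vw$weights)
  expect_gt(cor(log(mu), wbar, method = "spearman"), 0.5)
  ## count 0 in a tiny library stays finite through the 0.5 offset
  tiny <- matrix(c(0, 5, 10, 2), 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_true(all(is.finite(log_cpm(tiny))))
})
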