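#' Configuration for a synthetic acute-exercise cohort
#'
#' Encodes the study design the pipeline assumes: participants randomized
#' 3:8:8 to control (CON), endurance (EE) and resistance (RE); one
#' pre-exercise biopsy each plus post-exercise biopsies at 15min / 3.5h / 24h
#' according to a randomized timepoint arm (Early / Middle / Late / All).
#' Feature universes, effect sizes, noise and missingness for five omes are
#' configurable so every downstream stage can be validated against planted
#' ground truth.
#'
#' @param n_participants Number of participants (default 174, the size of a
#'   realistic pre-suspension cohort).
#' @param allocation_ratio Integer CON:EE:RE allocation ratio.
#' @param group_counts Optional named vector (`CON`, `EE`, `RE`) of realized
#'   group sizes, overriding largest-remainder rounding of the ratio.
#' @param arm_probs Named probabilities over arms Early/Middle/Late/All
#'   (must sum to 1). Arms are equiprobable by default; the allocation of the
#'   original study was not published.
#' @param n_genes,n_tfs,n_peaks,n_phosphosites,n_metabolites Feature counts.
#'   The first `n_tfs` genes are transcription factors.
#' @param n_pathways Number of synthetic pathway gene sets.
#' @param n_perturbed Named list, per-ome number of features carrying an
#'   injected group-by-time effect.
#' @param effect_size_grid Named list of candidate |delta-delta| effect
#'   magnitudes (log2 units) per ome.
#' @param missingness Named per-ome MCAR missing-cell fraction in [0, 1).
#' @param missing_mode `"mcar"` or `"censor"` (intensity-dependent,
#'   left-censored; applies to protein/phospho/metab only).
#' @param participant_sd SD of the per-feature participant random intercept
#'   (log2 units).
#' @param nb_dispersion Negative-binomial dispersion for count omes.
#' @param feature_sd_meanlog,feature_sd_sdlog Log-normal parameters for
#'   per-feature residual SDs of the continuous omes.
#' @param regulator_out_degree Mean out-degree of a TF-phosphosite regulator
#'   in the planted regulatory network.
#' @param edge_beta Coefficient tying a target transcript's log-mean to its
#'   regulator phosphosite (standardized), and a circuit peak to its TF site.
#' @param link_window Max |TSS distance| (bp) for a true peak-gene link.
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   config including this seed.
#' @return A validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_participants = 174,
                          allocation_ratio = c(3L, 8L, 8L),
                          group_counts = NULL,
                          arm_probs = c(Early = 0.25, Middle = 0.25,
                                        Late = 0.25, All = 0.25),
                          n_genes = 400, n_tfs = 25, n_peaks = 500,
                          n_phosphosites = 350, n_metabolites = 120,
                          n_pathways = 40,
                          n_perturbed = list(rna = 30, atac = 30,
                                             protein = 20, phospho = 30,
                                             metab = 15),
                          effect_size_grid = list(rna = c(1, 1.5, 2),
                                                  atac = c(1, 1.5),
                                                  protein = c(0.5, 1),
                                                  phospho = c(1, 1.5, 2),
                                                  metab = c(1, 1.5)),
                          missingness = c(rna = 0, atac = 0, protein = 0.1,
                                          phospho = 0.2, metab = 0.1),
                          missing_mode = c("mcar", "censor"),
                          participant_sd = 0.3,
                          nb_dispersion = 0.1,
                          feature_sd_meanlog = log(0.5),
                          feature_sd_sdlog = 0.3,
                          regulator_out_degree = 5,
                          edge_beta = 0.8,
                          link_window = 1e5,
                          seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(n_participants = as.integer(n_participants),
              allocation_ratio = as.integer(allocation_ratio),
              group_counts = group_counts,
              arm_probs = arm_probs,
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_peaks = as.integer(n_peaks),
              n_phosphosites = as.integer(n_phosphosites),
              n_metabolites = as.integer(n_metabolites),
              n_pathways = as.integer(n_pathways),
              n_perturbed = n_perturbed,
              effect_size_grid = effect_size_grid,
              missingness = missingness, missing_mode = missing_mode,
              participant_sd = participant_sd,
              nb_dispersion = nb_dispersion,
              feature_sd_meanlog = feature_sd_meanlog,
              feature_sd_sdlog = feature_sd_sdlog,
              regulator_out_degree = regulator_out_degree,
              edge_beta = edge_beta, link_window = link_window,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$allocation_ratio) != 3 || any(cfg$allocation_ratio <= 0))
    stop("allocation_ratio must be three positive integers")
  if (is.null(cfg$group_counts) &&
      cfg$n_participants < sum(cfg$allocation_ratio))
    stop("invalid config: n_participants (", cfg$n_participants,
         ") smaller than the sum of allocation_ratio entries (",
         sum(cfg$allocation_ratio), ")")
  if (!is.null(cfg$group_counts)) {
    if (!all(GROUPS %in% names(cfg$group_counts)))
      stop("group_counts must name CON, EE and RE")
  }
  if (abs(sum(cfg$arm_probs) - 1) > 1e-8 || any(cfg$arm_probs < 0))
    stop("arm_probs must be nonnegative and sum to 1")
  if (!setequal(names(cfg$arm_probs), ARMS))
    stop("arm_probs must be named Early/Middle/Late/All")
  counts <- c(cfg$n_genes, cfg$n_tfs, cfg$n_peaks, cfg$n_phosphosites,
              cfg$n_metabolites)
  if (any(counts <= 0)) stop("feature counts must be positive")
  if (cfg$n_tfs > cfg$n_genes) stop("n_tfs must be <= n_genes")
  if (any(cfg$missingness < 0) || any(cfg$missingness >= 1))
    stop("missingness fractions must lie in [0, 1)")
  invisible(cfg)
}

## largest-remainder apportionment of n into parts proportional to ratio
largest_remainder <- function(n, ratio) {
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate the sample design of a synthetic cohort
#'
#' Participants are apportioned to CON/EE/RE by largest-remainder rounding of
#' the allocation ratio (or fixed via `group_counts`), assigned a timepoint
#' arm by the configured probabilities, and given one pre sample plus the
#' post samples their arm dictates. Sex (72% female), age and processing
#' batch are attached as covariates. Deterministic under a fixed config seed.
#'
#' @param config A [cohort_config()].
#' @return A validated design data.frame (see [validate_design()]) with an
#'   extra `arm` column.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    if (!is.null(config$group_counts)) {
      sizes <- as.integer(config$group_counts[GROUPS])
    } else {
      sizes <- largest_remainder(config$n_participants,
                                 config$allocation_ratio)
    }
    n <- sum(sizes)
    participant_id <- sprintf("P%03d", seq_len(n))
    group <- rep(GROUPS, times = sizes)
    arm <- sample(ARMS, n, replace = TRUE,
                  prob = config$arm_probs[ARMS])
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.72, 0.28))
    age <- round(pmin(70, pmax(18, stats::rnorm(n, 41, 15))))
    ## processing batches are randomized across groups (as in real studies),
    ## so batch never aliases the group factor
    batch <- paste0("b", ceiling(sample(n) / 20))
    tp_of_arm <- list(Early = "15min", Middle = "3.5h", Late = "24h",
                      All = POST_TIMEPOINTS)
    rows <- lapply(seq_len(n), function(i) {
      tps <- c("pre", tp_of_arm[[arm[i]]])
      data.frame(sample_id = paste0(participant_id[i], "_", tps),
                 participant_id = participant_id[i], group = group[i],
                 timepoint = tps, sex = sex[i], age = age[i],
                 batch = batch[i], arm = arm[i], stringsAsFactors = FALSE)
    })
    design <- do.call(rbind, rows)
    rownames(design) <- NULL
    validate_design(design)
    design
  })
}

#' Generate planted ground truth for a synthetic cohort
#'
#' Lays out genes on one synthetic chromosome (`chrS`, BED-convention
#' coordinates), places ATAC peaks around transcription start sites, assigns
#' phosphosites to proteins (with extra sites on transcription factors),
#' draws a TF-phosphosite to target-gene regulatory network with a configured
#' mean out-degree, plants TF motifs in peaks linked to regulated genes
#' (cis-regulatory circuit truth), builds pathway gene sets, and selects the
#' features that will carry injected group-by-time effects. CON never carries
#' an injected effect.
#'
#' @param config A [cohort_config()].
#' @return List of class `SyntheticTruth`: `genes`, `peaks`,
#'   `peak_gene_links`, `phosphosites`, `tf_genes`, `regulatory_edges`,
#'   `motif_occupancy` (peak x TF binary matrix), `circuits` (planted true
#'   circuits), `pathways`, `metabolites`, `perturbed_features`.
#' @export
generate_truth <- function(config) {
  validate_config(config)
  with_seed(derive_seed(config$seed, 2L), {
    G <- config$n_genes
    gene_id <- sprintf("G%04d", seq_len(G))
    tss <- cumsum(50000 + round(stats::runif(G, -10000, 10000)))
    genes <- data.frame(gene_id = gene_id, chrom = "chrS", tss = tss,
                        strand = "+",
                        is_tf = seq_len(G) <= config$n_tfs,
                        stringsAsFactors = FALSE)
    tf_genes <- gene_id[genes$is_tf]

    ## phosphosites: guarantee >= 2 sites per TF, remainder random
    n_sites <- config$n_phosphosites
    if (n_sites < 2 * config$n_tfs)
      stop("n_phosphosites too small to place 2 sites per TF")
    host <- c(rep(tf_genes, each = 2),
              sample(gene_id, n_sites - 2 * config$n_tfs, replace = TRUE))
    residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                      prob = c(0.75, 0.15, 0.10))
    pos <- sample(1:999, n_sites, replace = TRUE)
    site_id <- paste0(host, "_", residue, pos)
    dup <- duplicated(site_id)
    while (any(dup)) {  # enforce unique ids
      pos[dup] <- sample(1:999, sum(dup), replace = TRUE)
      site_id <- paste0(host, "_", residue, pos)
      dup <- duplicated(site_id)
    }
    phosphosites <- data.frame(site_id = site_id, gene_id = host,
                               residue = residue, position = pos,
                               is_tf_site = host %in% tf_genes,
                               confident_score = stats::runif(n_sites, 10, 40),
                               stringsAsFactors = FALSE)

    ## regulatory edges: TF phosphosite -> non-TF target gene
    reg_sites <- phosphosites$site_id[phosphosites$is_tf_site]
    targets_pool <- gene_id[!genes$is_tf]
    edges <- lapply(reg_sites, function(s) {
      k <- stats::rpois(1, config$regulator_out_degree)
      k <- min(k, length(targets_pool))
      if (k == 0) return(NULL)
      data.frame(regulator = s,
                 target = sample(targets_pool, k),
                 stringsAsFactors = FALSE)
    })
    regulatory_edges <- do.call(rbind, edges)
    if (is.null(regulatory_edges))
      regulatory_edges <- data.frame(regulator = character(),
                                     target = character())

    ## peaks around TSSs; ~10% deliberately beyond the link window
    P <- config$n_peaks
    peak_gene <- sample(gene_id, P, replace = TRUE)
    kind <- sample(c("promoter", "distal", "far"), P, replace = TRUE,
                   prob = c(0.3, 0.6, 0.1))
    offset <- ifelse(kind == "promoter",
                     round(stats::runif(P, -900, 900)),
              ifelse(kind == "distal",
                     round(stats::runif(P, -config$link_window,
                                        config$link_window)),
                     sample(c(-1, 1), P, TRUE) *
                       round(stats::runif(P, config$link_window + 1000,
                                          2 * config$link_window))))
    center <- genes$tss[match(peak_gene, gene_id)] + offset
    peaks <- data.frame(peak_id = sprintf("peak%04d", seq_len(P)),
                        chrom = "chrS",
                        start = pmax(0, center - 100), end = center + 100,
                        gene_id = peak_gene, tss_distance = offset,
                        annotation = ifelse(abs(offset) <= 1000,
                                            "Promoter (<=1kb)", "Distal"),
                        stringsAsFactors = FALSE)
    links <- peaks[abs(peaks$tss_distance) <= config$link_window,
                   c("peak_id", "gene_id", "tss_distance")]

    ## plant circuits: a regulated target with a linked peak gets its
    ## regulator's TF motif in that peak
    motif <- matrix(stats::rbinom(P * config$n_tfs, 1, 0.05),
                    nrow = P, dimnames = list(peaks$peak_id, tf_genes))
    reg_tf <- phosphosites$gene_id[match(regulatory_edges$regulator,
                                         phosphosites$site_id)]
    circ <- NULL
    if (nrow(regulatory_edges)) {
      idx <- match(regulatory_edges$target, links$gene_id)
      has_peak <- !is.na(idx)
      circ <- data.frame(tf = reg_tf[has_peak],
                         regulator = regulatory_edges$regulator[has_peak],
                         peak_id = links$peak_id[idx[has_peak]],
                         gene_id = regulatory_edges$target[has_peak],
                         stringsAsFactors = FALSE)
      if (nrow(circ))
        motif[cbind(match(circ$peak_id, peaks$peak_id),
                    match(circ$tf, tf_genes))] <- 1L
    }
    if (is.null(circ))
      circ <- data.frame(tf = character(), regulator = character(),
                         peak_id = character(), gene_id = character())

    ## pathway gene sets
    pw_sizes <- sample(5:30, config$n_pathways, replace = TRUE)
    pathways <- lapply(pw_sizes, function(k) sample(gene_id, min(k, G)))
    names(pathways) <- sprintf("PW_%03d", seq_len(config$n_pathways))

    metabolites <- sprintf("met%04d", seq_len(config$n_metabolites))
    met_subclass <- sample(sprintf("subclass%02d", 1:10),
                           config$n_metabolites, replace = TRUE)

    ## perturbed features per ome (group x timepoint injected delta-delta)
    universes <- list(rna = gene_id, atac = peaks$peak_id,
                      protein = gene_id[seq_len(round(0.6 * G))],
                      phospho = phosphosites$site_id, metab = metabolites)
    pf <- lapply(names(universes), function(ome) {
      k <- config$n_perturbed[[ome]]
      if (is.null(k) || k == 0) return(NULL)
      k <- min(k, length(universes[[ome]]))
      data.frame(ome = ome,
                 feature_id = sample(universes[[ome]], k),
                 group = sample(c("EE", "RE"), k, replace = TRUE),
                 timepoint = sample(POST_TIMEPOINTS, k, replace = TRUE),
                 delta = sample(config$effect_size_grid[[ome]], k,
                                replace = TRUE) *
                         sample(c(-1, 1), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    perturbed <- do.call(rbind, pf)
    if (is.null(perturbed))
      perturbed <- data.frame(ome = character(), feature_id = character(),
                              group = character(), timepoint = character(),
                              delta = numeric())

    structure(list(genes = genes, peaks = peaks, peak_gene_links = links,
                   phosphosites = phosphosites, tf_genes = tf_genes,
                   regulatory_edges = regulatory_edges,
                   motif_occupancy = motif, circuits = circ,
                   pathways = pathways,
                   metabolites = data.frame(metabolite_id = metabolites,
                                            subclass = met_subclass,
                                            stringsAsFactors = FALSE),
                   protein_universe = universes$protein,
                   perturbed_features = perturbed,
                   config_seed = config$seed),
              class = "SyntheticTruth")
  })
}

## injected effects appear only as (group - CON) change-from-pre shifts:
## a delta is added to samples of the perturbed (group, timepoint) cell only
effect_shift <- function(feature_ids, ome, design, truth) {
  shift <- matrix(0, nrow = length(feature_ids), ncol = nrow(design),
                  dimnames = list(feature_ids, design$sample_id))
  pf <- truth$perturbed_features
  pf <- pf[pf$ome == ome & pf$feature_id %in% feature_ids, , drop = FALSE]
  if (nrow(pf) == 0) return(shift)
  for (i in seq_len(nrow(pf))) {
    cols <- design$group == pf$group[i] & design$timepoint == pf$timepoint[i]
    shift[pf$feature_id[i], cols] <- pf$delta[i]
  }
  shift
}

#' Simulate a multi-omic bundle from a design and planted truth
#'
#' RNA and ATAC are drawn negative-binomial with a per-feature participant
#' random intercept on the log2 scale; protein, phosphosite and metabolite
#' values are Gaussian on the log2 scale with per-feature variances drawn
#' from a log-normal. Planted regulatory edges make target transcripts depend
#' on their regulator phosphosite values, and planted circuits make linked
#' peaks depend on the TF site; injected effects are pure
#' group-by-timepoint shifts (so CON's expected change from pre is zero).
#' MCAR (or left-censored) missingness is applied per ome.
#'
#' @param design Output of [generate_cohort()].
#' @param truth Output of [generate_truth()] from the same config.
#' @param config The shared [cohort_config()].
#' @return List of class `SyntheticBundle` with elements `omics` (one
#'   [omics_matrix()] per ome), `design`, `truth`, `config`.
#' @export
simulate_omics <- function(design, truth, config) {
  validate_config(config)
  if (!inherits(truth, "SyntheticTruth") ||
      !identical(truth$config_seed, config$seed))
    stop("design/truth mismatch: truth was not generated from this config")
  validate_design(design)
  with_seed(derive_seed(config$seed, 3L), {
    S <- nrow(design)
    sample_id <- design$sample_id
    pidx <- match(design$participant_id, unique(design$participant_id))
    nP <- max(pidx)

    rand_intercepts <- function(n_feat) {
      b <- matrix(stats::rnorm(n_feat * nP, 0, config$participant_sd),
                  nrow = n_feat)
      b[, pidx, drop = FALSE]
    }
    feature_sds <- function(n_feat)
      stats::rlnorm(n_feat, config$feature_sd_meanlog, config$feature_sd_sdlog)

    ## --- phospho first: regulators feed downstream omes -------------------
    sites <- truth$phosphosites$site_id
    nF <- length(sites)
    sd_ph <- feature_sds(nF)
    ph <- rand_intercepts(nF) +
      matrix(stats::rnorm(nF * S, 0, rep(sd_ph, S)), nrow = nF) +
      effect_shift(sites, "phospho", design, truth)
    dimnames(ph) <- list(sites, sample_id)

    ## standardized regulator signal used by targets / circuit peaks
    reg_signal <- function(site) {
      v <- ph[site, ]
      (v - mean(v)) / max(stats::sd(v), 1e-8)
    }

    ## --- RNA counts -------------------------------------------------------
    genes <- truth$genes$gene_id
    nG <- length(genes)
    base_rna <- stats::rnorm(nG, 6, 1.5)
    logmu <- matrix(base_rna, nG, S) + rand_intercepts(nG) +
      effect_shift(genes, "rna", design, truth)
    dimnames(logmu) <- list(genes, sample_id)
    re <- truth$regulatory_edges
    if (nrow(re)) {
      for (i in seq_len(nrow(re))) {
        logmu[re$target[i], ] <- logmu[re$target[i], ] +
          config$edge_beta * reg_signal(re$regulator[i])
      }
    }
    rna <- matrix(stats::rnbinom(nG * S, mu = 2^logmu,
                                 size = 1 / config$nb_dispersion),
                  nrow = nG, dimnames = dimnames(logmu))

    ## --- ATAC counts ------------------------------------------------------
    pk <- truth$peaks$peak_id
    nK <- length(pk)
    logmu_a <- matrix(stats::rnorm(nK, 4, 1), nK, S) + rand_intercepts(nK) +
      effect_shift(pk, "atac", design, truth)
    dimnames(logmu_a) <- list(pk, sample_id)
    if (nrow(truth$circuits)) {
      for (i in seq_len(nrow(truth$circuits))) {
        logmu_a[truth$circuits$peak_id[i], ] <-
          logmu_a[truth$circuits$peak_id[i], ] +
          config$edge_beta * reg_signal(truth$circuits$regulator[i])
      }
    }
    atac <- matrix(stats::rnbinom(nK * S, mu = 2^logmu_a,
                                  size = 1 / config$nb_dispersion),
                   nrow = nK, dimnames = dimnames(logmu_a))

    ## --- protein log-ratios ----------------------------------------------
    prot_ids <- truth$protein_universe
    nPr <- length(prot_ids)
    sd_pr <- feature_sds(nPr)
    prot <- rand_intercepts(nPr) +
      matrix(stats::rnorm(nPr * S, 0, rep(sd_pr, S)), nrow = nPr) +
      effect_shift(prot_ids, "protein", design, truth)
    dimnames(prot) <- list(prot_ids, sample_id)

    ## --- metabolite abundances (positive scale) --------------------------
    met_ids <- truth$metabolites$metabolite_id
    nM <- length(met_ids)
    sd_m <- feature_sds(nM)
    logmet <- matrix(stats::rnorm(nM, 8, 1), nM, S) + rand_intercepts(nM) +
      matrix(stats::rnorm(nM * S, 0, rep(sd_m, S)), nrow = nM) +
      effect_shift(met_ids, "metab", design, truth)
    met <- 2^logmet
    dimnames(met) <- list(met_ids, sample_id)

    apply_missing <- function(x, frac, censor = FALSE) {
      if (frac <= 0) return(x)
      if (censor) {
        ## left-censored: lowest values most likely to drop out
        r <- apply(x, 1, rank, ties.method = "average")
        pmiss <- 2 * frac * (1 - t(r) / (ncol(x) + 1))
        drop <- matrix(stats::runif(length(x)) < pmiss, nrow = nrow(x))
      } else {
        drop <- matrix(stats::runif(length(x)) < frac, nrow = nrow(x))
      }
      x[drop] <- NA
      x
    }
    censor <- config$missing_mode == "censor"
    mfrac <- config$missingness
    rna  <- apply_missing(rna,  mfrac[["rna"]])
    atac <- apply_missing(atac, mfrac[["atac"]])
    prot <- apply_missing(prot, mfrac[["protein"]], censor)
    ph   <- apply_missing(ph,   mfrac[["phospho"]], censor)
    met  <- apply_missing(met,  mfrac[["metab"]],   censor)

    gene_meta <- truth$genes[, c("gene_id", "chrom", "tss", "is_tf")]
    site_meta <- truth$phosphosites
    omics <- list(
      rna = omics_matrix(rna, "rna",
                         data.frame(gene_id = genes, gene_meta[, -1])),
      atac = omics_matrix(atac, "atac",
                          truth$peaks[, c("peak_id", "chrom", "start", "end",
                                          "gene_id", "tss_distance",
                                          "annotation")]),
      protein = omics_matrix(prot, "protein",
                             data.frame(gene_id = prot_ids,
                                        stringsAsFactors = FALSE)),
      phospho = omics_matrix(ph, "phospho", site_meta),
      metab = omics_matrix(met, "metab", truth$metabolites)
    )
    structure(list(omics = omics, design = design, truth = truth,
                   config = config),
              class = "SyntheticBundle")
  })
}

#' Generate a complete synthetic bundle in one call
#'
#' @param config A [cohort_config()].
#' @return A `SyntheticBundle` (see [simulate_omics()]).
#' @export
simulate_bundle <- function(config) {
  design <- generate_cohort(config)
  truth <- generate_truth(config)
  simulate_omics(design, truth, config)
}
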