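#' Simulation settings for synthetic quantification data
#'
#' Defines the hierarchical generative model for MaxQuant-style peptide
#' tables with known ground truth. On the log2 scale a peptide's expected
#' intensity is
#' \code{protein baseline + peptide ionization offset + group effect (DE
#' proteins, experimental samples) + sample offset + noise}.
#' A cell is observed with probability
#' \code{plogis((intensity - detection_mid) / detection_scale)} -- detection
#' is monotone in intensity, making missingness intensity-dependent (MNAR).
#' Observed cells get a spectral count
#' \code{max(1, Poisson(count_rate * 2^((intensity - baseline_mean)/4)))}.
#' Decoy (reverse) entries and shared (two-group) peptides are appended.
#'
#' Defaults mirror a small two-group tissue cohort: 5 vs 4 experimental
#' samples, protein baselines Normal(25, 2), peptide offsets
#' Normal(0, 1.5), sample offsets Normal(0, 0.2), residual noise sd 0.4,
#' peptides per protein 1 + Poisson(6), and DE effects of +/-1 on the log2
#' scale (2-fold) with random sign. Optional technical (WTL-CTRL) and
#' biological (LCM-CTRL) replicate samples of one source can be added;
#' WTL replicates carry half the residual noise of biological samples.
#'
#' @param n_proteins Number of forward proteins.
#' @param peptides_per_protein_lambda Poisson rate; peptides per protein are
#'   \code{1 + Poisson(lambda)}.
#' @param n_samples_per_group Integer pair: experimental group sizes.
#' @param n_wtl_ctrl,n_lcm_ctrl Numbers of control replicate samples.
#' @param frac_de Fraction of DE proteins.
#' @param log2_effect Absolute DE effect size (sign randomized).
#' @param baseline_mean,baseline_sd Protein log2 baseline distribution.
#' @param peptide_offset_sd Peptide ionization offset sd.
#' @param sample_offset_sd Per-sample shift sd.
#' @param noise_sd Residual log2 noise sd.
#' @param detection_mid,detection_scale Logistic detection curve (log2
#'   midpoint and scale); \code{detection_scale = 0} means saturated
#'   detection (everything above/below the midpoint observed/unobserved).
#' @param count_rate Linear factor linking intensity to expected counts.
#' @param frac_shared_peptides Fraction of peptides assigned to two protein
#'   groups.
#' @param frac_reverse Decoy entries as a fraction of forward peptides.
#' @param seed Mandatory integer seed.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(n_proteins = 500L,
                              peptides_per_protein_lambda = 6,
                              n_samples_per_group = c(5L, 4L),
                              n_wtl_ctrl = 0L, n_lcm_ctrl = 0L,
                              frac_de = 0.1, log2_effect = 1,
                              baseline_mean = 25, baseline_sd = 2,
                              peptide_offset_sd = 1.5,
                              sample_offset_sd = 0.2, noise_sd = 0.4,
                              detection_mid = 21, detection_scale = 1,
                              count_rate = 2,
                              frac_shared_peptides = 0.05,
                              frac_reverse = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_proteins >= 1L, length(n_samples_per_group) == 2L,
            all(n_samples_per_group >= 1L),
            frac_de >= 0, frac_de <= 1,
            frac_shared_peptides >= 0, frac_shared_peptides <= 1,
            frac_reverse >= 0, frac_reverse <= 1,
            baseline_sd > 0, peptide_offset_sd >= 0,
            sample_offset_sd >= 0, noise_sd >= 0, detection_scale >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein_lambda = peptides_per_protein_lambda,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_wtl_ctrl = as.integer(n_wtl_ctrl),
                 n_lcm_ctrl = as.integer(n_lcm_ctrl),
                 frac_de = frac_de, log2_effect = log2_effect,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 peptide_offset_sd = peptide_offset_sd,
                 sample_offset_sd = sample_offset_sd, noise_sd = noise_sd,
                 detection_mid = detection_mid,
                 detection_scale = detection_scale,
                 count_rate = count_rate,
                 frac_shared_peptides = frac_shared_peptides,
                 frac_reverse = frac_reverse, seed = as.integer(seed)),
            class = "SimulationConfig")
}

.detection_prob <- function(log2_intensity, mid, scale) {
  if (scale == 0) return(as.numeric(log2_intensity >= mid))
  stats::plogis((log2_intensity - mid) / scale)
}

#' Generate a synthetic quantification dataset with known truth
#'
#' Draws a peptide table, the rolled-up protein table, the study design and
#' the ground truth from the model described in [simulation_config()].
#' The same seed always yields identical tables.
#'
#' @param config A \code{SimulationConfig}.
#' @return List with \code{peptides} (\code{PeptideQuantTable}),
#'   \code{proteins} (\code{ProteinQuantTable}, built by
#'   [rollup_protein_table()]), \code{design} (\code{StudyDesign}) and
#'   \code{truth} (list of class \code{SyntheticTruth}: per-protein
#'   \code{is_de}, \code{log2_effect}, expected log2 abundance matrix;
#'   per-peptide \code{parent} and \code{offset}; the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cfg) {
  n1 <- cfg$n_samples_per_group[1]
  n2 <- cfg$n_samples_per_group[2]
  exp_ids <- c(sprintf("ERpos_%02d", seq_len(n1)),
               sprintf("ERneg_%02d", seq_len(n2)))
  wtl_ids <- if (cfg$n_wtl_ctrl > 0) sprintf("WTL_%02d",
                                             seq_len(cfg$n_wtl_ctrl))
  else character(0)
  lcm_ids <- if (cfg$n_lcm_ctrl > 0) sprintf("LCM_%02d",
                                             seq_len(cfg$n_lcm_ctrl))
  else character(0)
  samples <- c(wtl_ids, lcm_ids, exp_ids)
  design <- study_design(
    samples,
    c(rep("WTL-CTRL", length(wtl_ids)), rep("LCM-CTRL", length(lcm_ids)),
      rep("EXPERIMENTAL", length(exp_ids))),
    c(rep("", length(wtl_ids) + length(lcm_ids)),
      rep("ER+", n1), rep("ER-", n2)))
  ns <- length(samples)
  is_exp <- design$sample_class == "EXPERIMENTAL"
  in_group2 <- design$group_label == "ER-"
  # per-sample technical shifts; WTL technical replicates vary least
  sample_shift <- stats::rnorm(ns, 0, cfg$sample_offset_sd)
  noise_factor <- ifelse(design$sample_class == "WTL-CTRL", 0.5, 1)

  P <- cfg$n_proteins
  baseline <- stats::rnorm(P, cfg$baseline_mean, cfg$baseline_sd)
  n_de <- round(cfg$frac_de * P)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, P - n_de))
  effect <- ifelse(is_de,
                   cfg$log2_effect * sample(c(-1, 1), P, replace = TRUE), 0)
  n_pep <- 1L + stats::rpois(P, cfg$peptides_per_protein_lambda)
  prot_ids <- sprintf("P%04d", seq_len(P))

  parent <- rep(seq_len(P), n_pep)
  n_pep_total <- length(parent)
  offset <- stats::rnorm(n_pep_total, 0, cfg$peptide_offset_sd)
  pep_keys <- sprintf("PEP%05d", seq_len(n_pep_total))
  # expected log2 per protein x sample (group effect applied to ER- group)
  expected <- outer(baseline, sample_shift, `+`)
  expected <- expected + outer(effect, as.numeric(is_exp & in_group2))
  colnames(expected) <- samples
  rownames(expected) <- prot_ids

  true_log2 <- expected[parent, , drop = FALSE] + offset +
    matrix(stats::rnorm(n_pep_total * ns, 0, cfg$noise_sd),
           n_pep_total, ns) *
      rep(noise_factor, each = n_pep_total)
  p_det <- .detection_prob(true_log2, cfg$detection_mid,
                           cfg$detection_scale)
  observed <- matrix(stats::runif(n_pep_total * ns), n_pep_total, ns) < p_det
  intensity <- ifelse(observed, 2^true_log2, NA_real_)
  colnames(intensity) <- samples
  lambda <- cfg$count_rate * 2^((true_log2 - cfg$baseline_mean) / 4)
  counts <- matrix(0L, n_pep_total, ns)
  counts[observed] <- pmax(1L, stats::rpois(sum(observed),
                                            lambda[observed]))
  colnames(counts) <- samples

  groups <- as.list(prot_ids[parent])
  n_shared <- round(cfg$frac_shared_peptides * n_pep_total)
  if (n_shared > 0 && P >= 2L) {
    shared_idx <- sample.int(n_pep_total, n_shared)
    for (i in shared_idx) {
      other <- sample(setdiff(seq_len(P), parent[i]), 1L)
      groups[[i]] <- c(groups[[i]], prot_ids[other])
    }
  }
  is_rev <- rep(FALSE, n_pep_total)
  n_rev <- round(cfg$frac_reverse * n_pep_total)
  if (n_rev > 0) {
    rev_keys <- sprintf("REVPEP%05d", seq_len(n_rev))
    rev_parent_ids <- sprintf("REV__P%04d",
                              sample.int(P, n_rev, replace = TRUE))
    rev_log2 <- stats::rnorm(n_rev, cfg$baseline_mean - 2, cfg$baseline_sd)
    rev_int <- matrix(NA_real_, n_rev, ns, dimnames = list(NULL, samples))
    rev_cnt <- matrix(0L, n_rev, ns, dimnames = list(NULL, samples))
    for (i in seq_len(n_rev)) {
      obs_cols <- which(stats::runif(ns) <
                          .detection_prob(rev_log2[i], cfg$detection_mid,
                                          cfg$detection_scale) * 0.5)
      rev_int[i, obs_cols] <- 2^(rev_log2[i] +
                                   stats::rnorm(length(obs_cols), 0,
                                                cfg$noise_sd))
      rev_cnt[i, obs_cols] <- 1L
    }
    pep_keys <- c(pep_keys, rev_keys)
    groups <- c(groups, as.list(rev_parent_ids))
    is_rev <- c(is_rev, rep(TRUE, n_rev))
    intensity <- rbind(intensity, rev_int)
    counts <- rbind(counts, rev_cnt)
  }
  # drop peptides never observed anywhere (they would not be in the file)
  seen <- rowSums(!is.na(intensity)) > 0
  peptides <- peptide_quant_table(pep_keys[seen],
                                  groups[seen],
                                  is_rev[seen],
                                  intensity[seen, , drop = FALSE],
                                  counts[seen, , drop = FALSE])
  proteins <- rollup_protein_table(peptides)
  truth <- structure(list(protein_group_id = prot_ids,
                          is_de = is_de, log2_effect = effect,
                          expected_log2 = expected,
                          peptide_parent = stats::setNames(
                            prot_ids[parent], sprintf("PEP%05d",
                                                      seq_len(n_pep_total))),
                          peptide_offset = offset,
                          config = cfg),
                     class = "SyntheticTruth")
  list(peptides = peptides, proteins = proteins, design = design,
       truth = truth)
}

#' Evaluate differential results against synthetic truth
#'
#' @param called Character vector of protein ids declared differentially
#'   expressed (e.g. the refined or consolidated set).
#' @param truth A \code{SyntheticTruth}.
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{empirical_fdr} (\code{FP/(TP+FP)}, 0 for an empty call set) and
#'   \code{power} (\code{TP/(TP+FN)}, \code{NA} without true positives).
#' @export
truth_eval <- function(called, truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  universe <- truth$protein_group_id
  called <- intersect(unique(called), universe)
  de <- universe[truth$is_de]
  tp <- length(intersect(called, de))
  fp <- length(setdiff(called, de))
  fn <- length(setdiff(de, called))
  tn <- length(universe) - tp - fp - fn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       empirical_fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
       power = if (length(de) == 0) NA_real_ else tp / length(de))
}
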