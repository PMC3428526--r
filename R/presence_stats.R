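#' Two-sided Fisher exact p for a 2x2 table
#'
#' Computes the two-sided p value of the 2x2 table
#' \code{[[a, b], [c, d]]} by full hypergeometric enumeration over the fixed
#' margins: all tables at least as extreme (probability not exceeding the
#' observed table's, with the conventional relative tolerance 1e-7) are
#' summed.
#'
#' @param a,b,c,d Non-negative integer cell counts (rows: feature / rest;
#'   columns: the two groups).
#' @return The two-sided p value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0L) return(1)
  support <- max(0L, r1 - (n - c1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact presence/absence test on spectral counts
#'
#' For every protein, builds the 2x2 table
#' \code{[[SpC_A, SpC_B], [Tot_A - SpC_A, Tot_B - SpC_B]]}, where
#' \code{SpC_g} is the protein's MS/MS count summed over group \code{g}'s
#' experimental samples and \code{Tot_g} the grand total over all proteins,
#' and computes the two-sided Fisher exact p. An alternative mode
#' (\code{mode = "detection"}) counts samples with/without a detected
#' abundance per group instead. Proteins with zero counts in both groups are
#' flagged invalid with p = 1.
#'
#' @param proteins A \code{ProteinQuantTable} (decoys already dropped, see
#'   [drop_reverse_proteins()]).
#' @param design A \code{StudyDesign} with two experimental groups.
#' @param alpha Significance cutoff for the presence flag (default 0.05).
#' @param mode \code{"counts"} (summed spectral counts vs library totals,
#'   default) or \code{"detection"} (detected/undetected samples per group).
#' @return Data frame with \code{protein_group_id, count_a, count_b,
#'   fisher_p, direction, valid_test, fisher_hit}; attribute
#'   \code{"groups"} records the group order.
#' @export
fisher_presence <- function(proteins, design, alpha = 0.05,
                            mode = c("counts", "detection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(proteins, "ProteinQuantTable"))
  if (any(proteins$is_reverse))
    stop("decoy rows present; call drop_reverse_proteins() first")
  grp <- .experimental_groups(design, sample_ids(proteins))
  if (mode == "counts") {
    cnt_a <- rowSums(proteins$msms_count[, grp$idx1, drop = FALSE])
    cnt_b <- rowSums(proteins$msms_count[, grp$idx2, drop = FALSE])
    tot_a <- sum(cnt_a)
    tot_b <- sum(cnt_b)
  } else {
    det <- !is.na(proteins$abundance)
    cnt_a <- rowSums(det[, grp$idx1, drop = FALSE])
    cnt_b <- rowSums(det[, grp$idx2, drop = FALSE])
  }
  n <- length(proteins$protein_group_id)
  p <- numeric(n)
  valid <- cnt_a + cnt_b > 0
  for (i in seq_len(n)) {
    if (!valid[i]) { p[i] <- 1; next }
    if (mode == "counts")
      p[i] <- fisher_exact_2x2(cnt_a[i], cnt_b[i],
                               tot_a - cnt_a[i], tot_b - cnt_b[i])
    else
      p[i] <- fisher_exact_2x2(cnt_a[i], cnt_b[i],
                               length(grp$idx1) - cnt_a[i],
                               length(grp$idx2) - cnt_b[i])
  }
  ref_a <- if (mode == "counts") tot_a else length(grp$idx1)
  ref_b <- if (mode == "counts") tot_b else length(grp$idx2)
  direction <- ifelse(cnt_a / ref_a >= cnt_b / ref_b,
                      grp$levels[1], grp$levels[2])
  direction[!valid] <- NA_character_
  out <- data.frame(protein_group_id = proteins$protein_group_id,
                    count_a = unname(cnt_a), count_b = unname(cnt_b),
                    fisher_p = p, direction = direction,
                    valid_test = valid,
                    fisher_hit = valid & p < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- grp$levels
  out
}

#' Imputation settings for downshifted-normal replacement
#'
#' Missing log2 abundances are replaced by draws from a normal distribution
#' shifted below each sample's observed distribution -- the standard model
#' for intensities missing because they fall under the detection limit.
#' Defaults: width 0.3 (imputed sd as a fraction of the sample's observed
#' sd) and downshift 1.8 (sds below the sample's observed mean).
#'
#' @param width Fraction of the per-sample observed sd (> 0).
#' @param downshift Number of observed sds below the observed mean (>= 0).
#' @param seed Integer seed for the draws.
#' @return A list of class \code{ImputationSpec}.
#' @export
imputation_spec <- function(width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(width > 0, downshift >= 0)
  structure(list(width = width, downshift = downshift,
                 seed = as.integer(seed)),
            class = "ImputationSpec")
}

#' Impute missing values from a downshifted normal distribution
#'
#' For each sample (column) with observed mean \code{m_s} and sd \code{d_s},
#' every missing cell is drawn independently from
#' \code{Normal(m_s - downshift * d_s, (width * d_s)^2)} using the seeded
#' generator. Observed cells are never modified. Cells are drawn in
#' row-major order (feature by feature, then sample by sample within the
#' row), so results are reproducible for a given seed.
#'
#' @param log2_matrix Log2 matrix (features x samples) with \code{NA} for
#'   missing; every sample needs >= 2 observed values.
#' @param spec An \code{ImputationSpec}.
#' @return The completed matrix.
#' @export
impute_downshifted_normal <- function(log2_matrix, spec = imputation_spec()) {
  m <- as.matrix(log2_matrix)
  miss <- is.na(m)
  if (!any(miss)) return(m)
  mu <- sd <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    obs <- m[, j][!is.na(m[, j])]
    if (length(obs) < 2L)
      stop("sample '", colnames(m)[j],
           "' has fewer than 2 observed values; cannot impute")
    mu[j] <- mean(obs)
    sd[j] <- stats::sd(obs)
  }
  # row-major draw order: transpose so missing cells enumerate row by row
  tm <- t(m)
  tmiss <- is.na(tm)
  idx <- which(tmiss)
  sample_of <- ((idx - 1L) %% nrow(tm)) + 1L
  draws <- withr::with_seed(spec$seed,
    stats::rnorm(length(idx),
                 mean = mu[sample_of] - spec$downshift * sd[sample_of],
                 sd = spec$width * sd[sample_of]))
  tm[idx] <- draws
  t(tm)
}

#' Run the presence/absence branch (Fisher pre-selection, imputed t-test)
#'
#' Branch 2 of the differential analysis: all forward proteins are tested by
#' the spectral-count Fisher exact test ([fisher_presence()]); the full
#' protein log2 matrix is then completed by downshifted-normal imputation
#' ([impute_downshifted_normal()]) and the Fisher-significant proteins are
#' confirmed by a Welch t test with permutation-based FDR on their imputed
#' abundances. The consolidated set requires the Fisher flag, t-test
#' p < \code{alpha_refine} and q <= \code{fdr}. Imputation is performed
#' once; permutations re-use the completed matrix.
#'
#' @param proteins A \code{ProteinQuantTable} (decoys dropped internally).
#' @param design A \code{StudyDesign} with two experimental groups.
#' @param spec An \code{ImputationSpec}.
#' @param alpha_fisher Fisher cutoff (default 0.05).
#' @param alpha_refine t-test cutoff (default 0.05).
#' @param fdr Permutation-FDR cutoff (default 0.05).
#' @param n_perm,seed Permutation settings, see [permutation_fdr()].
#' @param mode Fisher table mode, see [fisher_presence()].
#' @return A \code{DifferentialResults} data frame with per-protein Fisher
#'   and t statistics and flags \code{fisher_hit}, \code{consolidated}.
#' @export
run_presence_branch <- function(proteins, design, spec = imputation_spec(),
                                alpha_fisher = 0.05, alpha_refine = 0.05,
                                fdr = 0.05, n_perm = 250L, seed = 1L,
                                mode = "counts") {
  proteins <- drop_reverse_proteins(proteins)
  check_sample_axis(design, proteins = proteins)
  fis <- fisher_presence(proteins, design, alpha = alpha_fisher, mode = mode)
  exp_samples <- intersect(design_samples(design, "EXPERIMENTAL"),
                           sample_ids(proteins))
  prot_log2 <- log2_transform(proteins)[, exp_samples, drop = FALSE]
  imputed <- impute_downshifted_normal(prot_log2, spec)
  res <- fis
  res$t_statistic <- res$mean_diff <- res$p_ttest <- res$q_value <- NA_real_
  sel <- res$protein_group_id[res$fisher_hit]
  if (length(sel)) {
    sub <- imputed[sel, , drop = FALSE]
    tt <- group_ttest(sub, design)
    qv <- permutation_fdr(stats::setNames(tt$t_statistic, sel), sub, design,
                          n_perm = n_perm, seed = seed)
    m <- match(sel, res$protein_group_id)
    res$t_statistic[m] <- tt$t_statistic
    res$mean_diff[m] <- tt$mean_diff
    res$p_ttest[m] <- tt$p_value
    res$q_value[m] <- qv
  }
  res$consolidated <- res$fisher_hit & !is.na(res$p_ttest) &
    res$p_ttest < alpha_refine & !is.na(res$q_value) & res$q_value <= fdr
  entry <- proteins$entry_names[match(res$protein_group_id,
                                      proteins$protein_group_id)]
  res$entry_names <- vapply(entry, function(e)
    if (is.null(e)) "" else paste(e, collapse = ";"), "")
  attr(res, "groups") <- attr(fis, "groups")
  class(res) <- c("DifferentialResults", "data.frame")
  res
}

#' Overlap between the two differential branches
#'
#' Compares the abundance branch's refined set with the presence branch's
#' consolidated set over the same protein universe: intersection, per-branch
#' exclusives, and -- for shared proteins -- whether the direction of
#' regulation agrees (sign of the abundance-branch mean difference versus
#' the group carrying the spectral-count excess).
#'
#' @param results_abundance \code{DifferentialResults} from
#'   [run_abundance_branch()].
#' @param results_presence \code{DifferentialResults} from
#'   [run_presence_branch()].
#' @return List with \code{shared}, \code{only_abundance},
#'   \code{only_presence} (character vectors of protein ids),
#'   \code{concordant} (named logical over the shared set) and
#'   \code{n_concordant}.
#' @export
branch_overlap <- function(results_abundance, results_presence) {
  set_a <- results_abundance$protein_group_id[results_abundance$refined]
  set_p <- results_presence$protein_group_id[results_presence$consolidated]
  shared <- intersect(set_a, set_p)
  groups <- attr(results_abundance, "groups")
  conc <- logical(0)
  if (length(shared)) {
    md <- results_abundance$mean_diff[
      match(shared, results_abundance$protein_group_id)]
    dir_p <- results_presence$direction[
      match(shared, results_presence$protein_group_id)]
    # mean_diff is group2 - group1: positive means up in groups[2]
    dir_a <- ifelse(md >= 0, groups[2], groups[1])
    conc <- stats::setNames(dir_a == dir_p, shared)
  }
  list(shared = shared,
       only_abundance = setdiff(set_a, set_p),
       only_presence = setdiff(set_p, set_a),
       concordant = conc,
       n_concordant = sum(conc))
}
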