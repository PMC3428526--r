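#' Select the most abundant peptides of a protein
#'
#' Ranks a protein's peptides by the median of their observed log2
#' intensities and keeps the top \code{k} (all rows when fewer). Ties at the
#' cutoff are broken lexicographically by peptide key, so selection is
#' deterministic.
#'
#' @param log2_rows Numeric matrix (peptides x samples) of log2 intensities
#'   with row names = peptide keys.
#' @param k Maximum number of peptides to keep (default 10).
#' @return The selected rows, in rank order.
#' @export
select_top_peptides <- function(log2_rows, k = 10L) {
  if (nrow(log2_rows) == 0L) stop("no peptide rows for this protein")
  med <- apply(log2_rows, 1, function(v)
    if (all(is.na(v))) -Inf else stats::median(v, na.rm = TRUE))
  ord <- order(-med, rownames(log2_rows), method = "radix")
  log2_rows[ord[seq_len(min(k, nrow(log2_rows)))], , drop = FALSE]
}

# Huber-weighted IRLS fit of y ~ X. Returns coefficients (NA = aliased),
# weighted residual variance, (X'WX)^-1 on estimable columns, rank, and a
# convergence flag. With robust = FALSE this is one OLS pass.
.irls_fit <- function(X, y, robust = TRUE, k_huber = 1.345,
                      max_iter = 50L, tol = 1e-8) {
  n <- length(y)
  w <- rep(1, n)
  beta_old <- NULL
  converged <- !robust
  for (iter in seq_len(if (robust) max_iter else 1L)) {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    r <- drop(y - X[, !is.na(beta), drop = FALSE] %*% beta[!is.na(beta)])
    if (!robust) break
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-10) { converged <- TRUE; break }   # (near-)perfect fit
    u <- abs(r / s)
    w <- ifelse(u <= k_huber, 1, k_huber / u)
    if (!is.null(beta_old)) {
      delta <- max(abs(ifelse(is.na(beta), 0, beta) -
                       ifelse(is.na(beta_old), 0, beta_old)))
      if (delta < tol) { converged <- TRUE; break }
    }
    beta_old <- beta
  }
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  est <- !is.na(beta)
  Xe <- X[, est, drop = FALSE]
  r <- drop(y - Xe %*% beta[est])
  rank <- fit$rank
  df <- n - rank
  sigma2 <- if (df > 0) sum(w * r^2) / df else 0
  XtWX <- crossprod(Xe * sqrt(w))
  cov_unscaled <- tryCatch(solve(XtWX), error = function(e) NULL)
  list(beta = beta, est = est, sigma2 = sigma2,
       cov_unscaled = cov_unscaled, df = df, converged = converged)
}

#' Peptide-level robust ANOVA for one protein
#'
#' Fits, on the observed log2 cells of a protein's (top-ranked) peptides
#' across the two experimental groups, the fixed-effects model
#' \code{log2 abundance = intercept + group + peptide + error} by iteratively
#' reweighted least squares with Huber weighting (tuning constant 1.345, at
#' most 50 iterations, coefficient-change tolerance 1e-8). The group effect
#' (second group minus first) is tested with a Wald t on
#' \code{n_obs - rank} residual degrees of freedom. Sample-level batch shifts
#' are assumed removed upstream by per-sample median centering. With one
#' peptide and \code{robust = FALSE} this reduces to the classical
#' pooled-variance two-sample t test.
#'
#' Peptide columns made collinear by missingness are dropped automatically
#' (rank-deficient fits use pivoted least squares); if the group effect
#' itself is inestimable the result carries \code{converged = FALSE} and a
#' missing p value.
#'
#' @param log2_rows Peptide log2 matrix (peptides x samples), experimental
#'   samples only.
#' @param group Factor/character of group labels, one per column.
#' @param robust Use Huber IRLS (default) or plain least squares.
#' @return List with \code{group_effect}, \code{p_value},
#'   \code{n_peptides_used}, \code{converged}.
#' @export
fit_me_anova <- function(log2_rows, group, robust = TRUE) {
  stopifnot(ncol(log2_rows) == length(group))
  lev <- sort(unique(as.character(group)), method = "radix")
  if (length(lev) != 2L) stop("exactly two groups are required")
  obs <- which(!is.na(log2_rows), arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("no observed cells")
  y <- log2_rows[obs]
  g <- as.integer(as.character(group)[obs[, 2]] == lev[2])
  pep <- factor(rownames(log2_rows)[obs[, 1]],
                levels = rownames(log2_rows))
  pep <- droplevels(pep)
  for (l in lev) if (sum(g == (l == lev[2])) < 2L)
    return(list(group_effect = NA_real_, p_value = NA_real_,
                n_peptides_used = nlevels(pep), converged = FALSE))
  X <- cbind(`(Intercept)` = 1, group = g)
  if (nlevels(pep) > 1L)
    X <- cbind(X, stats::model.matrix(~pep)[, -1, drop = FALSE])
  fit <- .irls_fit(X, y, robust = robust)
  beta_g <- fit$beta["group"]
  if (is.na(beta_g) || is.null(fit$cov_unscaled))
    return(list(group_effect = NA_real_, p_value = NA_real_,
                n_peptides_used = nlevels(pep), converged = FALSE))
  gi <- match("group", colnames(X)[fit$est])
  se <- sqrt(fit$sigma2 * fit$cov_unscaled[gi, gi])
  if (fit$df <= 0) {
    p <- NA_real_
  } else if (se < 1e-10 || !is.finite(se)) {
    p <- if (abs(beta_g) < 1e-8) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(beta_g / se), df = fit$df)
  }
  list(group_effect = unname(beta_g), p_value = unname(p),
       n_peptides_used = nlevels(pep), converged = fit$converged)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p values by the step-up rule
#' \code{adj_(i) = min_{j >= i} p_(j) * m / j}, capped at 1, with the
#' original order restored. Missing entries are excluded from \code{m} and
#' stay missing.
#'
#' @param p Numeric vector of p values in [0, 1], \code{NA} allowed.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("domain error: p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0L) return(out)
  ord <- order(p[idx])
  ranked <- p[idx][ord]
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  out[idx[ord]] <- pmin(adj, 1)
  out
}

# Welch t statistics row-wise for matrix columns split into two index sets.
# Returns t, mean difference (set2 - set1), df, and per-row obs counts.
.welch_rows <- function(X, idx1, idx2, min_per_group = 2L) {
  X1 <- X[, idx1, drop = FALSE]
  X2 <- X[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(X1))
  n2 <- rowSums(!is.na(X2))
  s1 <- rowSums(X1, na.rm = TRUE)
  s2 <- rowSums(X2, na.rm = TRUE)
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- pmax(0, (rowSums(X1^2, na.rm = TRUE) - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, (rowSums(X2^2, na.rm = TRUE) - n2 * m2^2) / (n2 - 1))
  d <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  t <- d / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  zero <- !is.na(se2) & se2 == 0
  t[zero] <- ifelse(abs(d[zero]) < 1e-12, 0, sign(d[zero]) * Inf)
  df[zero] <- n1[zero] + n2[zero] - 2
  bad <- n1 < min_per_group | n2 < min_per_group
  t[bad] <- NA
  df[bad] <- NA
  d[bad] <- NA
  list(t = t, mean_diff = d, df = df, n1 = n1, n2 = n2)
}

#' Welch two-sample t test on protein abundances
#'
#' Two-sided unequal-variance t test per protein row, computed over observed
#' values. Proteins with fewer than \code{min_per_group} observations in
#' either group get a missing p value (such presence/absence patterns are
#' the domain of the spectral-count branch). Zero variance in both groups
#' with equal means yields \code{t = 0, p = 1}.
#'
#' @param log2_abundance Protein log2 matrix (proteins x samples).
#' @param design A \code{StudyDesign}; the two experimental groups are
#'   compared (in design order, difference = second minus first).
#' @param min_per_group Minimum observations per group (default 2).
#' @return Data frame with \code{protein_group_id, t_statistic, p_value,
#'   mean_diff, n1, n2}.
#' @export
group_ttest <- function(log2_abundance, design, min_per_group = 2L) {
  grp <- .experimental_groups(design, colnames(log2_abundance))
  w <- .welch_rows(log2_abundance, grp$idx1, grp$idx2, min_per_group)
  p <- 2 * stats::pt(-abs(w$t), df = w$df)
  p[!is.na(w$t) & is.infinite(w$t)] <- 0
  p[!is.na(w$t) & w$t == 0 & !is.na(w$df)] <-
    2 * stats::pt(0, df = w$df[!is.na(w$t) & w$t == 0 & !is.na(w$df)])
  data.frame(protein_group_id = rownames(log2_abundance),
             t_statistic = unname(w$t), p_value = unname(p),
             mean_diff = unname(w$mean_diff),
             n1 = unname(w$n1), n2 = unname(w$n2),
             stringsAsFactors = FALSE)
}

# resolve the two experimental groups and their column indices
.experimental_groups <- function(design, sample_cols) {
  exp_rows <- design[design$sample_class == "EXPERIMENTAL" &
                       design$sample_id %in% sample_cols, , drop = FALSE]
  lev <- sort(unique(exp_rows$group_label), method = "radix")
  if (length(lev) != 2L)
    stop("exactly two experimental groups are required, found: ",
         paste(lev, collapse = ", "))
  idx1 <- match(exp_rows$sample_id[exp_rows$group_label == lev[1]],
                sample_cols)
  idx2 <- match(exp_rows$sample_id[exp_rows$group_label == lev[2]],
                sample_cols)
  list(levels = lev, idx1 = idx1, idx2 = idx2)
}

#' Permutation-based false discovery rate for t statistics
#'
#' Estimates, SAM-style, a q value for every protein: group labels are
#' permuted (all distinct label assignments are enumerated, excluding the
#' identity and -- for balanced designs -- its mirror image, whenever their
#' number does not exceed \code{n_perm}; otherwise \code{n_perm} assignments
#' are drawn with the given seed), the t statistic is recomputed for every
#' permutation, and for each protein
#' \code{q = mean_perm #\{|t_perm| >= |t|\} / #\{|t_obs| >= |t|\}}.
#' The q values are then made monotone non-increasing in |t| (running
#' minimum from the least to the most significant protein) and capped at 1.
#'
#' @param t_obs Observed t statistics (named by protein; \code{NA} allowed).
#' @param log2_abundance The matrix the statistics were computed from.
#' @param design A \code{StudyDesign}.
#' @param n_perm Maximum number of permutations (>= 10; default 250).
#' @param seed Integer seed used when permutations must be sampled.
#' @param min_per_group Passed through to the Welch computation.
#' @return Numeric vector of q values aligned with \code{t_obs}.
#' @export
permutation_fdr <- function(t_obs, log2_abundance, design, n_perm = 250L,
                            seed = 1L, min_per_group = 2L) {
  if (n_perm < 10L) stop("configuration error: n_perm must be >= 10")
  grp <- .experimental_groups(design, colnames(log2_abundance))
  idx_all <- sort(c(grp$idx1, grp$idx2))
  n1 <- length(grp$idx1)
  n <- length(idx_all)
  sets <- utils::combn(idx_all, n1)
  is_identity <- apply(sets, 2, function(s) setequal(s, grp$idx1))
  drop <- is_identity
  if (n1 == n - n1)
    drop <- drop | apply(sets, 2, function(s) setequal(s, grp$idx2))
  sets <- sets[, !drop, drop = FALSE]
  if (ncol(sets) > n_perm)
    sets <- withr::with_seed(seed,
      sets[, sample.int(ncol(sets), n_perm), drop = FALSE])
  abs_obs <- abs(t_obs)
  ok <- !is.na(abs_obs)
  q <- rep(NA_real_, length(t_obs))
  if (!any(ok) || ncol(sets) == 0L) return(q)
  thresholds <- abs_obs[ok]
  sorted_thr <- sort(thresholds)
  # observed exceedances per threshold
  n_obs_ge <- length(thresholds) -
    findInterval(thresholds, sorted_thr, left.open = TRUE)
  # permuted exceedances, accumulated over permutations
  num <- numeric(length(thresholds))
  for (k in seq_len(ncol(sets))) {
    s1 <- sets[, k]
    s2 <- setdiff(idx_all, s1)
    tp <- .welch_rows(log2_abundance, s1, s2, min_per_group)$t
    tp <- abs(tp[!is.na(tp)])
    if (!length(tp)) next
    sp <- sort(tp)
    num <- num + (length(sp) -
                    findInterval(thresholds, sp, left.open = TRUE))
  }
  qraw <- (num / ncol(sets)) / n_obs_ge
  # monotone non-increasing in |t|: running min from weakest to strongest
  ord <- order(thresholds)
  qs <- qraw[ord]
  qs <- cummin(qs)
  qraw[ord] <- qs
  q[ok] <- pmin(qraw, 1)
  q
}

#' Run the abundance branch (robust ANOVA pre-selection, t-test refinement)
#'
#' Branch 1 of the differential analysis: every protein with at least one
#' filtered peptide is tested by the peptide-level robust ANOVA
#' ([fit_me_anova()]) on its top-\code{top_k} most abundant peptides;
#' p values are Benjamini-Hochberg adjusted and proteins with adjusted
#' p < \code{alpha_pre} form the pre-selection. Pre-selected proteins are
#' refined by a Welch t test on their protein-level log2 abundances with a
#' permutation-based FDR: the refined set requires t-test
#' p < \code{alpha_refine} and q <= \code{fdr}.
#'
#' @param peptides A filtered \code{PeptideQuantTable} (see
#'   [filter_peptides()]); intensities on the linear scale.
#' @param proteins A \code{ProteinQuantTable} of LFQ abundances.
#' @param design A \code{StudyDesign} with two experimental groups.
#' @param alpha_pre Cutoff on adjusted ANOVA p (default 0.05).
#' @param alpha_refine Cutoff on refinement t-test p (default 0.05).
#' @param fdr Permutation-FDR cutoff (default 0.05).
#' @param top_k Maximum peptides per protein (default 10).
#' @param n_perm,seed Permutation settings, see [permutation_fdr()].
#' @param robust Huber weighting in the ANOVA fit (default TRUE).
#' @param center Median-center peptide log2 columns first (default TRUE).
#' @return A \code{DifferentialResults} data frame: one row per tested
#'   protein with all intermediate statistics and logical flags
#'   \code{preselected}, \code{refined}. Attribute \code{"groups"} records
#'   the group order (effects are second minus first).
#' @export
run_abundance_branch <- function(peptides, proteins, design,
                                 alpha_pre = 0.05, alpha_refine = 0.05,
                                 fdr = 0.05, top_k = 10L, n_perm = 250L,
                                 seed = 1L, robust = TRUE, center = TRUE) {
  check_sample_axis(design, peptides = peptides, proteins = proteins)
  exp_samples <- intersect(design_samples(design, "EXPERIMENTAL"),
                           sample_ids(peptides))
  pep_log2 <- log2_transform(peptides)
  if (center) pep_log2 <- median_center(pep_log2)
  pep_log2 <- pep_log2[, exp_samples, drop = FALSE]
  grp <- .experimental_groups(design, exp_samples)
  group_per_col <- character(length(exp_samples))
  group_per_col[grp$idx1] <- grp$levels[1]
  group_per_col[grp$idx2] <- grp$levels[2]
  assigned <- vapply(peptides$protein_group_ids, function(g)
    if (length(g) == 1L) g else NA_character_, "")
  prots <- unique(assigned[!is.na(assigned)])
  res <- data.frame(protein_group_id = prots,
                    n_peptides_used = NA_integer_,
                    group_effect = NA_real_, p_meanova = NA_real_,
                    converged = NA, stringsAsFactors = FALSE)
  for (i in seq_along(prots)) {
    rows <- which(assigned == prots[i])
    top <- select_top_peptides(pep_log2[rows, , drop = FALSE], top_k)
    fit <- tryCatch(fit_me_anova(top, group_per_col, robust = robust),
                    error = function(e) list(group_effect = NA_real_,
                                             p_value = NA_real_,
                                             n_peptides_used = nrow(top),
                                             converged = FALSE))
    res$n_peptides_used[i] <- fit$n_peptides_used
    res$group_effect[i] <- fit$group_effect
    res$p_meanova[i] <- fit$p_value
    res$converged[i] <- fit$converged
  }
  res$p_adjusted <- bh_adjust(res$p_meanova)
  res$preselected <- !is.na(res$p_adjusted) & res$p_adjusted < alpha_pre
  # refinement on protein-level abundances of the pre-selected set
  prot_log2 <- log2_transform(proteins)[, exp_samples, drop = FALSE]
  res$t_statistic <- res$mean_diff <- res$p_ttest <- res$q_value <- NA_real_
  sel <- res$protein_group_id[res$preselected]
  sel <- intersect(sel, rownames(prot_log2))
  if (length(sel)) {
    sub <- prot_log2[sel, , drop = FALSE]
    tt <- group_ttest(sub, design)
    qv <- permutation_fdr(stats::setNames(tt$t_statistic, sel), sub, design,
                          n_perm = n_perm, seed = seed)
    m <- match(sel, res$protein_group_id)
    res$t_statistic[m] <- tt$t_statistic
    res$mean_diff[m] <- tt$mean_diff
    res$p_ttest[m] <- tt$p_value
    res$q_value[m] <- qv
  }
  res$refined <- res$preselected & !is.na(res$p_ttest) &
    res$p_ttest < alpha_refine & !is.na(res$q_value) & res$q_value <= fdr
  entry <- proteins$entry_names[match(res$protein_group_id,
                                      proteins$protein_group_id)]
  res$entry_names <- vapply(entry, function(e)
    if (is.null(e)) "" else paste(e, collapse = ";"), "")
  res <- res[, c("protein_group_id", "entry_names", "n_peptides_used",
                 "group_effect", "p_meanova", "p_adjusted", "converged",
                 "t_statistic", "mean_diff", "p_ttest", "q_value",
                 "preselected", "refined")]
  attr(res, "groups") <- grp$levels
  class(res) <- c("DifferentialResults", "data.frame")
  res
}
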