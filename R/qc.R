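#' Per-sample identification counts
#'
#' Counts, for every sample, the features with an observed (non-missing)
#' intensity: the operational definition of "identified in that sample".
#' For peptide tables the count is also split into unique-only peptides.
#'
#' @param x A \code{PeptideQuantTable} or \code{ProteinQuantTable}.
#' @param design Optional \code{StudyDesign} (axis check only).
#' @return Data frame with \code{sample_id}, \code{n_total} and, for
#'   peptides, \code{n_unique}.
#' @export
identification_counts <- function(x, design = NULL) {
  if (!is.null(design)) {
    if (inherits(x, "PeptideQuantTable")) check_sample_axis(design, peptides = x)
    else check_sample_axis(design, proteins = x)
  }
  m <- if (inherits(x, "PeptideQuantTable")) x$intensity else x$abundance
  out <- data.frame(sample_id = colnames(m),
                    n_total = unname(colSums(!is.na(m))),
                    stringsAsFactors = FALSE)
  if (inherits(x, "PeptideQuantTable"))
    out$n_unique <- unname(colSums(!is.na(m[x$is_unique, , drop = FALSE])))
  out
}

#' Mean, sd and CV% of per-sample counts within a class
#'
#' @param counts Data frame from [identification_counts()].
#' @param design A \code{StudyDesign}.
#' @param sample_class The class to summarise.
#' @param column Which count column (default \code{"n_total"}).
#' @return List with \code{n}, \code{mean}, \code{sd}, \code{cv_pct}
#'   (\code{sd} and \code{cv_pct} are \code{NA} for classes with < 2
#'   samples).
#' @export
count_summary <- function(counts, design, sample_class,
                          column = "n_total") {
  ids <- design_samples(design, sample_class = sample_class)
  v <- counts[[column]][counts$sample_id %in% ids]
  if (length(v) == 0L) stop("no samples of class ", sample_class)
  if (length(v) < 2L)
    return(list(n = length(v), mean = mean(v), sd = NA_real_,
                cv_pct = NA_real_))
  list(n = length(v), mean = mean(v), sd = stats::sd(v),
       cv_pct = 100 * stats::sd(v) / mean(v))
}

#' Pairwise Pearson correlations within a sample class
#'
#' For every pair of class samples, the Pearson correlation of log2
#' abundances over positions observed in both. Pairs sharing fewer than 3
#' positions are set missing (with a warning) and excluded from the summary
#' over the \code{choose(n, 2)} distinct pairs.
#'
#' @param log2_matrix Log2 matrix (features x samples).
#' @param design A \code{StudyDesign}.
#' @param sample_class Class whose samples are correlated.
#' @return List with \code{cor} (correlation matrix, unit diagonal),
#'   \code{mean}, \code{sd} over distinct pairs.
#' @export
pairwise_pearson <- function(log2_matrix, design, sample_class) {
  ids <- intersect(design_samples(design, sample_class = sample_class),
                   colnames(log2_matrix))
  if (length(ids) < 2L) stop("need >= 2 samples of class ", sample_class)
  x <- log2_matrix[, ids, drop = FALSE]
  n <- length(ids)
  cm <- matrix(1, n, n, dimnames = list(ids, ids))
  vals <- numeric(0)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    shared <- !is.na(x[, i]) & !is.na(x[, j])
    if (sum(shared) < 3L) {
      warning("pair ", ids[i], "/", ids[j], " shares < 3 observations")
      cm[i, j] <- cm[j, i] <- NA_real_
      next
    }
    r <- stats::cor(x[shared, i], x[shared, j])
    cm[i, j] <- cm[j, i] <- r
    vals <- c(vals, r)
  }
  list(cor = cm, mean = mean(vals),
       sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_)
}

#' Reproducibility tiers of feature identifications
#'
#' Classifies every feature observed in at least one sample of a class by
#' its observation fraction \code{f = n_observed / n_class}: low when
#' \code{f <= 1/3}, high when \code{f >= 2/3}, medium otherwise (matching
#' the <=33 % / 34-66 % / >=67 % bands). Returns the fraction of features
#' per tier; the three fractions sum to 1.
#'
#' @param x A \code{PeptideQuantTable} or \code{ProteinQuantTable}.
#' @param design A \code{StudyDesign}.
#' @param sample_class The class to evaluate.
#' @return List with \code{n_features} and fractions \code{low},
#'   \code{medium}, \code{high}.
#' @export
reproducibility_tiers <- function(x, design, sample_class) {
  m <- if (inherits(x, "PeptideQuantTable")) x$intensity else x$abundance
  ids <- intersect(design_samples(design, sample_class = sample_class),
                   colnames(m))
  if (length(ids) < 2L) stop("need >= 2 samples of class ", sample_class)
  obs <- rowSums(!is.na(m[, ids, drop = FALSE]))
  f <- obs[obs > 0] / length(ids)
  n <- length(f)
  list(n_features = n,
       low = sum(f <= 1 / 3) / n,
       medium = sum(f > 1 / 3 & f < 2 / 3) / n,
       high = sum(f >= 2 / 3) / n)
}

#' Per-feature coefficients of variation on the linear scale
#'
#' For every feature observed in at least 2 samples of the class, the CV%
#' of its linear-scale (non-log) intensities: \code{100 * sd / mean}.
#'
#' @param x A \code{PeptideQuantTable} or \code{ProteinQuantTable}.
#' @param design A \code{StudyDesign}.
#' @param sample_class The class to evaluate.
#' @return List with \code{cv_pct} (per-feature vector), \code{mean},
#'   \code{sd}.
#' @export
feature_cv <- function(x, design, sample_class) {
  m <- if (inherits(x, "PeptideQuantTable")) x$intensity else x$abundance
  ids <- intersect(design_samples(design, sample_class = sample_class),
                   colnames(m))
  sub <- m[, ids, drop = FALSE]
  n_obs <- rowSums(!is.na(sub))
  keep <- n_obs >= 2L
  sub <- sub[keep, , drop = FALSE]
  mu <- rowMeans(sub, na.rm = TRUE)
  sdv <- apply(sub, 1, stats::sd, na.rm = TRUE)
  cv <- 100 * sdv / mu
  list(cv_pct = cv, mean = mean(cv),
       sd = if (length(cv) >= 2L) stats::sd(cv) else NA_real_)
}

#' Overlap of two identification sets
#'
#' @param set_a,set_b Character vectors of feature ids (e.g. protein groups
#'   identified in two sample classes).
#' @return List with sizes of union, intersection and exclusives, plus
#'   percentages of the union.
#' @export
set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- union(set_a, set_b)
  i <- intersect(set_a, set_b)
  oa <- setdiff(set_a, set_b)
  ob <- setdiff(set_b, set_a)
  pct <- function(k) if (length(u)) 100 * k / length(u) else NA_real_
  list(n_union = length(u), n_shared = length(i),
       n_only_a = length(oa), n_only_b = length(ob),
       pct_shared = pct(length(i)), pct_only_a = pct(length(oa)),
       pct_only_b = pct(length(ob)),
       shared = i, only_a = oa, only_b = ob)
}

#' Features identified anywhere in a sample class
#' @param x A \code{PeptideQuantTable} or \code{ProteinQuantTable}.
#' @param design A \code{StudyDesign}.
#' @param sample_class The class.
#' @return Character vector of feature ids observed in >= 1 class sample.
#' @export
class_feature_set <- function(x, design, sample_class) {
  m <- if (inherits(x, "PeptideQuantTable")) x$intensity else x$abundance
  ids <- intersect(design_samples(design, sample_class = sample_class),
                   colnames(m))
  rownames(m)[rowSums(!is.na(m[, ids, drop = FALSE])) > 0]
}

#' Full replicate-QC report
#'
#' Runs the whole QC battery for every sample class present in the design
#' (identification counts with class summaries, pairwise Pearson
#' correlations, reproducibility tiers, per-feature CVs) at both peptide and
#' protein level, plus the protein-set overlap between the two control
#' classes when both exist.
#'
#' @param peptides A \code{PeptideQuantTable}.
#' @param proteins A \code{ProteinQuantTable}.
#' @param design A \code{StudyDesign}.
#' @return A nested list of class \code{QCReport}.
#' @export
qc_report <- function(peptides, proteins, design) {
  check_sample_axis(design, peptides = peptides, proteins = proteins)
  classes <- intersect(c("WTL-CTRL", "LCM-CTRL", "EXPERIMENTAL"),
                       unique(design$sample_class))
  pep_counts <- identification_counts(peptides)
  prot_counts <- identification_counts(proteins)
  pep_log2 <- log2_transform(peptides)
  prot_log2 <- log2_transform(proteins)
  per_class <- list()
  for (cl in classes) {
    n_cl <- length(design_samples(design, sample_class = cl))
    entry <- list(
      n_samples = n_cl,
      peptide_counts = count_summary(pep_counts, design, cl),
      unique_peptide_counts = count_summary(pep_counts, design, cl,
                                            column = "n_unique"),
      protein_counts = count_summary(prot_counts, design, cl))
    if (n_cl >= 2L) {
      entry$peptide_pearson <- pairwise_pearson(pep_log2, design, cl)
      entry$protein_pearson <- pairwise_pearson(prot_log2, design, cl)
      entry$peptide_tiers <- reproducibility_tiers(peptides, design, cl)
      entry$protein_tiers <- reproducibility_tiers(proteins, design, cl)
      entry$peptide_cv <- feature_cv(peptides, design, cl)
      entry$protein_cv <- feature_cv(proteins, design, cl)
    }
    per_class[[cl]] <- entry
  }
  overlap <- NULL
  if (all(c("WTL-CTRL", "LCM-CTRL") %in% classes))
    overlap <- set_overlap(class_feature_set(proteins, design, "WTL-CTRL"),
                           class_feature_set(proteins, design, "LCM-CTRL"))
  structure(list(per_class = per_class, control_overlap = overlap),
            class = "QCReport")
}

#' Write a QC report as a multi-section TSV
#' @param report A \code{QCReport}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  rows <- list()
  add <- function(section, class_label, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, sample_class = class_label, metric = metric,
      value = value, stringsAsFactors = FALSE)
  for (cl in names(report$per_class)) {
    e <- report$per_class[[cl]]
    for (fam in c("peptide_counts", "unique_peptide_counts",
                  "protein_counts"))
      for (k in c("mean", "sd", "cv_pct"))
        add("identification", cl, paste(fam, k, sep = "."), e[[fam]][[k]])
    for (fam in c("peptide_pearson", "protein_pearson", "peptide_cv",
                  "protein_cv"))
      if (!is.null(e[[fam]]))
        for (k in c("mean", "sd"))
          add("reproducibility", cl, paste(fam, k, sep = "."), e[[fam]][[k]])
    for (fam in c("peptide_tiers", "protein_tiers"))
      if (!is.null(e[[fam]]))
        for (k in c("low", "medium", "high"))
          add("tiers", cl, paste(fam, k, sep = "."), e[[fam]][[k]])
  }
  if (!is.null(report$control_overlap))
    for (k in c("n_union", "n_shared", "n_only_a", "n_only_b",
                "pct_shared", "pct_only_a", "pct_only_b"))
      add("overlap", "WTL-CTRL/LCM-CTRL", k, report$control_overlap[[k]])
  write_results_table(do.call(rbind, rows), path)
}
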