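#' Log2-transform a quantification matrix
#'
#' Maps observed linear-scale values to log2; missing cells stay missing.
#' Accepts a \code{PeptideQuantTable}, \code{ProteinQuantTable} or a plain
#' matrix, and returns a log-abundance matrix (features x samples) with
#' attribute \code{centered = FALSE}.
#'
#' @param x Table or matrix of linear-scale values with \code{NA} for missing.
#' @return A numeric matrix of log2 abundances with attribute
#'   \code{centered}.
#' @export
log2_transform <- function(x) {
  m <- if (inherits(x, "PeptideQuantTable")) x$intensity
  else if (inherits(x, "ProteinQuantTable")) x$abundance
  else as.matrix(x)
  obs <- !is.na(m)
  if (any(m[obs] <= 0))
    stop("domain error: observed values must be > 0 before log2 transform")
  m[obs] <- log2(m[obs])
  attr(m, "centered") <- FALSE
  m
}

#' Median-center a log2 matrix per sample
#'
#' Subtracts, from every sample column, the median of its observed values so
#' that each sample's observed median becomes 0. Missing cells are untouched.
#' Idempotent.
#'
#' @param m Log2 matrix (features x samples) with \code{NA} for missing.
#' @return The centered matrix, with attribute \code{centered = TRUE}.
#' @export
median_center <- function(m) {
  m <- as.matrix(m)
  for (j in seq_len(ncol(m))) {
    obs <- m[, j][!is.na(m[, j])]
    if (length(obs) == 0L)
      stop("sample '", colnames(m)[j], "' has no observed values to center")
    m[, j] <- m[, j] - stats::median(obs)
  }
  attr(m, "centered") <- TRUE
  m
}

#' Peptide filtering criteria
#'
#' The inclusion rules applied before peptide-level differential testing:
#' (a) the peptide is unique to one protein group, (b) it is not a decoy
#' (reversed-sequence) hit, and (c) it is observed in at least
#' \code{ceiling(min_obs_fraction * n)} of the reference samples. The default
#' fraction is 0.5, reproducing the 5-of-9 rule for a 9-sample cohort; for
#' large cohorts (n > 60) a fraction of 0.3 is a documented alternative.
#'
#' @param require_unique Drop peptides mapping to more than one protein group.
#' @param drop_reverse Drop decoy (reverse) peptides.
#' @param min_obs_fraction Minimum fraction of reference samples with an
#'   observation, in (0, 1].
#' @param reference_sample_set Which design classes count toward the
#'   observation threshold (default the experimental cohort).
#' @return A list of class \code{FilterCriteria}.
#' @export
filter_criteria <- function(require_unique = TRUE, drop_reverse = TRUE,
                            min_obs_fraction = 0.5,
                            reference_sample_set = "EXPERIMENTAL") {
  stopifnot(min_obs_fraction > 0, min_obs_fraction <= 1)
  structure(list(require_unique = require_unique,
                 drop_reverse = drop_reverse,
                 min_obs_fraction = min_obs_fraction,
                 reference_sample_set = reference_sample_set),
            class = "FilterCriteria")
}

#' Filter peptides for differential testing
#'
#' Applies the criteria in [filter_criteria()] and returns the retained
#' peptides together with a filter report (rows dropped per criterion,
#' attached as attribute \code{"filter_report"}). The observation count for
#' criterion (c) is taken over the reference sample set (by default the
#' experimental samples), with threshold
#' \code{ceiling(min_obs_fraction * n_ref)}.
#'
#' @param peptides A \code{PeptideQuantTable}.
#' @param design A \code{StudyDesign}.
#' @param criteria A \code{FilterCriteria}.
#' @return The filtered \code{PeptideQuantTable}; attribute
#'   \code{"filter_report"} holds a data frame (criterion, rows_dropped).
#' @export
filter_peptides <- function(peptides, design, criteria = filter_criteria()) {
  stopifnot(inherits(peptides, "PeptideQuantTable"))
  check_sample_axis(design, peptides = peptides)
  keep <- rep(TRUE, length(peptides$peptide_key))
  dropped <- c(non_unique = 0L, reverse = 0L, low_observation = 0L)
  if (criteria$require_unique) {
    bad <- keep & !peptides$is_unique
    dropped["non_unique"] <- sum(bad)
    keep <- keep & !bad
  }
  if (criteria$drop_reverse) {
    bad <- keep & peptides$is_reverse
    dropped["reverse"] <- sum(bad)
    keep <- keep & !bad
  }
  ref <- design_samples(design, sample_class = criteria$reference_sample_set)
  ref <- intersect(ref, sample_ids(peptides))
  if (length(ref) == 0L)
    stop("no reference samples of class ",
         paste(criteria$reference_sample_set, collapse = "/"),
         " present in the peptide table")
  min_obs <- ceiling(criteria$min_obs_fraction * length(ref))
  n_obs <- rowSums(!is.na(peptides$intensity[, ref, drop = FALSE]))
  bad <- keep & (n_obs < min_obs)
  dropped["low_observation"] <- sum(bad)
  keep <- keep & !bad
  if (!any(keep)) warning("peptide filter removed every row")
  out <- subset_peptides(peptides, keep)
  attr(out, "filter_report") <- data.frame(
    criterion = names(dropped), rows_dropped = as.integer(dropped),
    stringsAsFactors = FALSE)
  out
}

#' Subset a peptide table by row
#' @param peptides A \code{PeptideQuantTable}.
#' @param i Logical or integer row index.
#' @return The subset \code{PeptideQuantTable}.
#' @export
subset_peptides <- function(peptides, i) {
  peptide_quant_table(peptides$peptide_key[i],
                      peptides$protein_group_ids[i],
                      peptides$is_reverse[i],
                      peptides$intensity[i, , drop = FALSE],
                      peptides$msms_count[i, , drop = FALSE])
}

#' Subset a protein table by row
#' @param proteins A \code{ProteinQuantTable}.
#' @param i Logical or integer row index.
#' @return The subset \code{ProteinQuantTable}.
#' @export
subset_proteins <- function(proteins, i) {
  protein_quant_table(proteins$protein_group_id[i],
                      proteins$entry_names[i],
                      proteins$is_reverse[i],
                      proteins$abundance[i, , drop = FALSE],
                      proteins$msms_count[i, , drop = FALSE])
}

#' Drop decoy (reverse) protein groups
#'
#' Removes rows flagged as reversed-sequence hits; all remaining (forward)
#' identifications are kept, whatever their missingness.
#'
#' @param proteins A \code{ProteinQuantTable}.
#' @return The \code{ProteinQuantTable} without decoy rows.
#' @export
drop_reverse_proteins <- function(proteins) {
  stopifnot(inherits(proteins, "ProteinQuantTable"))
  if (!any(proteins$is_reverse)) return(proteins)
  keep <- !proteins$is_reverse
  if (!any(keep)) warning("all protein groups are decoys; result is empty")
  subset_proteins(proteins, keep)
}
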