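#' Median log2 peptide ratio between two samples
#'
#' For one protein's peptide rows (log2 scale), the ratio edge between
#' samples \code{a} and \code{b} is the median over peptides observed in both
#' of (log2 intensity in a - log2 intensity in b). The edge is undefined when
#' fewer than \code{min_shared} peptides are shared.
#'
#' @param log2_rows Numeric matrix (peptides x samples) of log2 intensities
#'   with \code{NA} for missing, restricted to one protein group's
#'   razor/unique peptides.
#' @param a,b Sample ids or column indices.
#' @param min_shared Minimum number of shared peptides for a defined edge.
#' @return List with \code{ratio} (or \code{NA} if undefined) and
#'   \code{support} (number of shared peptides).
#' @export
pairwise_median_ratio <- function(log2_rows, a, b, min_shared = 1L) {
  la <- log2_rows[, a]
  lb <- log2_rows[, b]
  shared <- !is.na(la) & !is.na(lb)
  support <- sum(shared)
  if (support < min_shared) return(list(ratio = NA_real_, support = support))
  list(ratio = stats::median(la[shared] - lb[shared]), support = support)
}

#' Build the pairwise ratio graph for one protein
#'
#' Nodes are samples; an edge carries the median log2 peptide ratio between
#' two samples (see [pairwise_median_ratio()]). Antisymmetry
#' \code{r[a,b] = -r[b,a]} holds exactly because each unordered pair is
#' evaluated once.
#'
#' @inheritParams pairwise_median_ratio
#' @return List of class \code{RatioGraph}: \code{ratio} and \code{support}
#'   matrices (samples x samples) and the sample ids.
#' @export
ratio_graph <- function(log2_rows, min_shared = 1L) {
  s <- colnames(log2_rows)
  n <- length(s)
  r <- matrix(NA_real_, n, n, dimnames = list(s, s))
  supp <- matrix(0L, n, n, dimnames = list(s, s))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    e <- pairwise_median_ratio(log2_rows, i, j, min_shared)
    supp[i, j] <- supp[j, i] <- e$support
    if (!is.na(e$ratio)) {
      r[i, j] <- e$ratio
      r[j, i] <- -e$ratio
    }
  }
  structure(list(ratio = r, support = supp, samples = s),
            class = "RatioGraph")
}

# connected components over defined edges; isolated samples with evidence
# form singleton components
.graph_components <- function(has_edge, has_evidence) {
  n <- nrow(has_edge)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v]) || !has_evidence[v]) next
    k <- k + 1L
    queue <- v
    comp[v] <- k
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(has_edge[u, ] & is.na(comp) & has_evidence)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Solve per-sample protein log2 abundances from a ratio graph
#'
#' Within each connected component of the graph, per-sample values minimise
#' the sum of squared edge residuals \code{(x_a - x_b - r[a,b])^2}. The free
#' additive constant of each component is anchored so that the mean of the
#' solved values equals the mean of the observed per-sample median peptide
#' log2 intensities of that component, tying the result to the absolute
#' intensity scale. Samples with no observed peptide are \code{NA}.
#'
#' @param graph A \code{RatioGraph}.
#' @param log2_rows The peptide log2 matrix the graph was built from.
#' @return Named numeric vector of per-sample log2 abundances (\code{NA}
#'   where unquantifiable).
#' @export
solve_abundances <- function(graph, log2_rows) {
  s <- graph$samples
  n <- length(s)
  med_obs <- apply(log2_rows, 2, function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  has_evidence <- !is.na(med_obs)
  has_edge <- !is.na(graph$ratio)
  comp <- .graph_components(has_edge, has_evidence)
  x <- rep(NA_real_, n)
  names(x) <- s
  for (k in seq_len(max(comp, 0L, na.rm = TRUE))) {
    members <- which(comp == k)
    m <- length(members)
    if (m == 1L) {
      x[members] <- med_obs[members]
      next
    }
    # least squares on the graph Laplacian, gauge fixed by mean-zero
    L <- matrix(0, m, m)
    b <- numeric(m)
    for (ii in seq_len(m - 1L)) for (jj in (ii + 1L):m) {
      u <- members[ii]; v <- members[jj]
      if (!has_edge[u, v]) next
      L[ii, ii] <- L[ii, ii] + 1
      L[jj, jj] <- L[jj, jj] + 1
      L[ii, jj] <- L[ii, jj] - 1
      L[jj, ii] <- L[jj, ii] - 1
      b[ii] <- b[ii] + graph$ratio[u, v]
      b[jj] <- b[jj] - graph$ratio[u, v]
    }
    sol <- solve(L + matrix(1 / m, m, m), b)   # enforces mean(sol) = 0
    x[members] <- sol - mean(sol) + mean(med_obs[members])
  }
  x
}

#' Roll peptide intensities up to protein abundances
#'
#' Reconstructs a per-sample protein abundance profile for every protein
#' group with at least one razor-or-unique peptide, using the pairwise
#' median-ratio graph and its least-squares solution, then converts back to
#' the linear scale. Per-sample protein spectral counts are the sums of the
#' member peptides' counts. Non-unique peptides are assigned, razor-style, to
#' the first protein group in their assignment list.
#'
#' @param peptides A \code{PeptideQuantTable} (decoys are rolled up into
#'   decoy protein groups, preserving the flag).
#' @param design Optional \code{StudyDesign} for the axis check.
#' @param min_shared Minimum shared peptides behind a ratio edge.
#' @return A \code{ProteinQuantTable}.
#' @export
rollup_protein_table <- function(peptides, design = NULL, min_shared = 1L) {
  stopifnot(inherits(peptides, "PeptideQuantTable"))
  if (!is.null(design)) check_sample_axis(design, peptides = peptides)
  log2_all <- log2_transform(peptides)
  razor_group <- vapply(peptides$protein_group_ids, function(g)
    if (length(g)) g[1] else NA_character_, "")
  keep <- !is.na(razor_group)
  groups <- unique(razor_group[keep])
  samples <- sample_ids(peptides)
  ab <- matrix(NA_real_, length(groups), length(samples),
               dimnames = list(groups, samples))
  counts <- matrix(0L, length(groups), length(samples),
                   dimnames = list(groups, samples))
  is_rev <- logical(length(groups))
  for (gi in seq_along(groups)) {
    rows <- which(razor_group == groups[gi])
    g <- ratio_graph(log2_all[rows, , drop = FALSE], min_shared)
    ab[gi, ] <- solve_abundances(g, log2_all[rows, , drop = FALSE])
    counts[gi, ] <- as.integer(colSums(
      peptides$msms_count[rows, , drop = FALSE]))
    is_rev[gi] <- all(peptides$is_reverse[rows])
  }
  protein_quant_table(groups, as.list(groups), is_rev, 2^ab, counts)
}
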