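#' MaxQuant-style table dialect
#'
#' Column-name conventions used when reading and writing peptide and protein
#' quantification tables. Defaults match the tab-delimited output of early
#' MaxQuant versions: per-sample column families \code{"Intensity <sample>"},
#' \code{"LFQ intensity <sample>"} and \code{"MS/MS Count <sample>"}, a decoy
#' column \code{"Reverse"} marked with \code{"+"}, and a \code{"Proteins"}
#' column holding \code{";"}-separated protein-group identifiers.
#'
#' @param sequence_col Name of the peptide sequence column.
#' @param proteins_col Name of the protein-group assignment column
#'   (peptide tables).
#' @param protein_id_col Name of the protein-group identifier column
#'   (protein tables).
#' @param entry_col Name of the database entry-name column (protein tables).
#' @param reverse_col Name of the decoy flag column.
#' @param reverse_marker Marker string denoting a decoy row.
#' @param intensity_prefix Prefix of per-sample raw intensity columns.
#' @param lfq_prefix Prefix of per-sample LFQ abundance columns.
#' @param msms_prefix Prefix of per-sample MS/MS (spectral) count columns.
#' @param id_sep Separator inside multi-valued identifier cells.
#' @return A named list of dialect options.
#' @export
mq_dialect <- function(sequence_col = "Sequence",
                       proteins_col = "Proteins",
                       protein_id_col = "Protein IDs",
                       entry_col = "Entry name",
                       reverse_col = "Reverse",
                       reverse_marker = "+",
                       intensity_prefix = "Intensity ",
                       lfq_prefix = "LFQ intensity ",
                       msms_prefix = "MS/MS Count ",
                       id_sep = ";") {
  list(sequence_col = sequence_col, proteins_col = proteins_col,
       protein_id_col = protein_id_col, entry_col = entry_col,
       reverse_col = reverse_col, reverse_marker = reverse_marker,
       intensity_prefix = intensity_prefix, lfq_prefix = lfq_prefix,
       msms_prefix = msms_prefix, id_sep = id_sep)
}

#' Construct a peptide quantification table
#'
#' The in-memory representation of a \code{peptides.txt}-style table: one row
#' per peptide sequence, per-sample linear-scale intensities (\code{NA} for
#' not observed -- never 0), per-sample spectral counts, the protein-group
#' assignment, and decoy/uniqueness flags.
#'
#' @param peptide_key Character vector of unique peptide sequences.
#' @param protein_group_ids List of character vectors: the protein group(s)
#'   each peptide maps to, in assignment order.
#' @param is_reverse Logical decoy flags.
#' @param intensity Numeric matrix (peptides x samples) of linear intensities;
#'   \code{NA} means not observed.
#' @param msms_count Integer matrix of spectral counts, same shape.
#' @return An object of class \code{PeptideQuantTable}.
#' @export
peptide_quant_table <- function(peptide_key, protein_group_ids, is_reverse,
                                intensity, msms_count = NULL) {
  peptide_key <- as.character(peptide_key)
  if (anyDuplicated(peptide_key))
    stop("duplicate peptide_key: ",
         paste(unique(peptide_key[duplicated(peptide_key)]), collapse = ", "))
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(msms_count))
    msms_count <- matrix(0L, nrow(intensity), ncol(intensity),
                         dimnames = dimnames(intensity))
  msms_count <- as.matrix(msms_count)
  storage.mode(msms_count) <- "integer"
  n <- length(peptide_key)
  stopifnot(length(protein_group_ids) == n, length(is_reverse) == n,
            nrow(intensity) == n, all(dim(msms_count) == dim(intensity)))
  if (is.null(colnames(intensity)))
    stop("intensity matrix must carry sample ids as column names")
  if (any(intensity[!is.na(intensity)] <= 0))
    stop("observed intensities must be > 0 (zeros encode missingness)")
  if (any(is.na(msms_count)) || any(msms_count < 0L))
    stop("msms_count must be non-negative integers")
  rownames(intensity) <- rownames(msms_count) <- peptide_key
  colnames(msms_count) <- colnames(intensity)
  protein_group_ids <- lapply(protein_group_ids, as.character)
  structure(list(peptide_key = peptide_key,
                 protein_group_ids = protein_group_ids,
                 is_unique = lengths(protein_group_ids) == 1L,
                 is_reverse = as.logical(is_reverse),
                 intensity = intensity,
                 msms_count = msms_count),
            class = "PeptideQuantTable")
}

#' Construct a protein quantification table
#'
#' One row per protein group, with per-sample linear-scale abundances
#' (\code{NA} for missing), summed spectral counts, database entry names
#' and a decoy flag.
#'
#' @param protein_group_id Character vector of unique protein-group ids.
#' @param entry_names List of character vectors of database entry names.
#' @param is_reverse Logical decoy flags.
#' @param abundance Numeric matrix (proteins x samples), \code{NA} = missing.
#' @param msms_count Integer matrix of spectral counts, same shape.
#' @return An object of class \code{ProteinQuantTable}.
#' @export
protein_quant_table <- function(protein_group_id, entry_names, is_reverse,
                                abundance, msms_count = NULL) {
  protein_group_id <- as.character(protein_group_id)
  if (anyDuplicated(protein_group_id))
    stop("duplicate protein_group_id: ",
         paste(unique(protein_group_id[duplicated(protein_group_id)]),
               collapse = ", "))
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(msms_count))
    msms_count <- matrix(0L, nrow(abundance), ncol(abundance),
                         dimnames = dimnames(abundance))
  msms_count <- as.matrix(msms_count)
  storage.mode(msms_count) <- "integer"
  n <- length(protein_group_id)
  stopifnot(length(entry_names) == n, length(is_reverse) == n,
            nrow(abundance) == n, all(dim(msms_count) == dim(abundance)))
  if (is.null(colnames(abundance)))
    stop("abundance matrix must carry sample ids as column names")
  if (any(abundance[!is.na(abundance)] <= 0))
    stop("observed abundances must be > 0 (zeros encode missingness)")
  rownames(abundance) <- rownames(msms_count) <- protein_group_id
  colnames(msms_count) <- colnames(abundance)
  structure(list(protein_group_id = protein_group_id,
                 entry_names = lapply(entry_names, as.character),
                 is_reverse = as.logical(is_reverse),
                 abundance = abundance,
                 msms_count = msms_count),
            class = "ProteinQuantTable")
}

#' @export
print.PeptideQuantTable <- function(x, ...) {
  cat("PeptideQuantTable:", length(x$peptide_key), "peptides x",
      ncol(x$intensity), "samples\n")
  cat("  unique:", sum(x$is_unique), " reverse:", sum(x$is_reverse),
      " observed cells:", sum(!is.na(x$intensity)), "\n")
  invisible(x)
}

#' @export
print.ProteinQuantTable <- function(x, ...) {
  cat("ProteinQuantTable:", length(x$protein_group_id), "protein groups x",
      ncol(x$abundance), "samples\n")
  cat("  reverse:", sum(x$is_reverse),
      " observed cells:", sum(!is.na(x$abundance)), "\n")
  invisible(x)
}

#' Sample ids of a quantification table
#' @param x A \code{PeptideQuantTable} or \code{ProteinQuantTable}.
#' @return Character vector of sample ids (column order).
#' @export
sample_ids <- function(x) {
  if (inherits(x, "PeptideQuantTable")) return(colnames(x$intensity))
  if (inherits(x, "ProteinQuantTable")) return(colnames(x$abundance))
  stop("not a quantification table")
}

.sample_cols <- function(header, prefix) {
  hit <- startsWith(header, prefix)
  list(cols = header[hit], samples = substring(header[hit], nchar(prefix) + 1L))
}

.parse_numeric_cells <- function(df, cols, path, what) {
  m <- matrix(NA_real_, nrow(df), length(cols))
  for (j in seq_along(cols)) {
    raw <- df[[cols[j]]]
    if (is.numeric(raw)) { m[, j] <- raw; next }
    raw <- trimws(as.character(raw))
    raw[raw == ""] <- NA
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad))
      stop(sprintf("non-numeric %s cell in '%s': row %d, column '%s' ('%s')",
                   what, path, bad[1], cols[j], raw[bad[1]]))
    m[, j] <- val
  }
  m
}

#' Read a MaxQuant-style peptide table
#'
#' Reads a tab-delimited \code{peptides.txt}-style file. Zero and blank
#' intensity cells become \code{NA} (in this dialect 0 means "not observed").
#' Uniqueness is derived from the protein-group assignment column; the decoy
#' flag from the reverse-marker column. Row order is preserved.
#'
#' @param path Path to the tab-delimited file.
#' @param dialect Dialect options, see [mq_dialect()].
#' @return A \code{PeptideQuantTable}.
#' @export
read_peptide_table <- function(path, dialect = mq_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c(dialect$sequence_col, dialect$proteins_col))
    if (!col %in% names(df))
      stop(sprintf("format error in '%s': missing mandatory column '%s'",
                   path, col))
  ints <- .sample_cols(names(df), dialect$intensity_prefix)
  if (length(ints$cols) == 0L)
    stop(sprintf("format error in '%s': no '%s<sample>' columns found",
                 path, dialect$intensity_prefix))
  key <- df[[dialect$sequence_col]]
  if (anyDuplicated(key))
    stop(sprintf("data error in '%s': duplicate peptide_key '%s'",
                 path, key[duplicated(key)][1]))
  intensity <- .parse_numeric_cells(df, ints$cols, path, "intensity")
  intensity[!is.na(intensity) & intensity == 0] <- NA
  colnames(intensity) <- ints$samples
  msms <- .sample_cols(names(df), dialect$msms_prefix)
  msms_count <- NULL
  if (length(msms$cols)) {
    msms_count <- .parse_numeric_cells(df, msms$cols, path, "MS/MS count")
    msms_count[is.na(msms_count)] <- 0
    msms_count <- msms_count[, match(ints$samples, msms$samples), drop = FALSE]
    colnames(msms_count) <- ints$samples
  }
  rev_flag <- if (dialect$reverse_col %in% names(df))
    !is.na(df[[dialect$reverse_col]]) &
      trimws(df[[dialect$reverse_col]]) == dialect$reverse_marker
  else rep(FALSE, nrow(df))
  groups <- strsplit(df[[dialect$proteins_col]], dialect$id_sep, fixed = TRUE)
  groups <- lapply(groups, function(g) trimws(g[nzchar(trimws(g))]))
  peptide_quant_table(key, groups, rev_flag, intensity, msms_count)
}

#' Read a MaxQuant-style protein-group table
#'
#' Reads a tab-delimited \code{proteinGroups.txt}-style file; abundances come
#' from the LFQ-intensity column family. All-zero rows are retained with all
#' abundances \code{NA}.
#'
#' @inheritParams read_peptide_table
#' @return A \code{ProteinQuantTable}.
#' @export
read_protein_table <- function(path, dialect = mq_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!dialect$protein_id_col %in% names(df))
    stop(sprintf("format error in '%s': missing mandatory column '%s'",
                 path, dialect$protein_id_col))
  lfq <- .sample_cols(names(df), dialect$lfq_prefix)
  if (length(lfq$cols) == 0L)
    stop(sprintf("format error in '%s': no '%s<sample>' columns found",
                 path, dialect$lfq_prefix))
  id <- df[[dialect$protein_id_col]]
  if (anyDuplicated(id))
    stop(sprintf("data error in '%s': duplicate protein_group_id '%s'",
                 path, id[duplicated(id)][1]))
  abundance <- .parse_numeric_cells(df, lfq$cols, path, "LFQ intensity")
  abundance[!is.na(abundance) & abundance == 0] <- NA
  colnames(abundance) <- lfq$samples
  msms <- .sample_cols(names(df), dialect$msms_prefix)
  msms_count <- NULL
  if (length(msms$cols)) {
    msms_count <- .parse_numeric_cells(df, msms$cols, path, "MS/MS count")
    msms_count[is.na(msms_count)] <- 0
    msms_count <- msms_count[, match(lfq$samples, msms$samples), drop = FALSE]
    colnames(msms_count) <- lfq$samples
  }
  rev_flag <- if (dialect$reverse_col %in% names(df))
    !is.na(df[[dialect$reverse_col]]) &
      trimws(df[[dialect$reverse_col]]) == dialect$reverse_marker
  else rep(FALSE, nrow(df))
  entries <- if (dialect$entry_col %in% names(df))
    lapply(strsplit(df[[dialect$entry_col]], dialect$id_sep, fixed = TRUE),
           function(g) trimws(g[nzchar(trimws(g))]))
  else rep(list(character(0)), nrow(df))
  protein_quant_table(id, entries, rev_flag, abundance, msms_count)
}

#' Write a peptide table in the MaxQuant-style dialect
#' @param x A \code{PeptideQuantTable}.
#' @param path Output path.
#' @param dialect Dialect options, see [mq_dialect()].
#' @return Invisibly, \code{path}.
#' @export
write_peptide_table <- function(x, path, dialect = mq_dialect()) {
  stopifnot(inherits(x, "PeptideQuantTable"))
  ints <- x$intensity
  ints[is.na(ints)] <- 0
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   a = x$peptide_key,
                   b = vapply(x$protein_group_ids, paste,
                              collapse = dialect$id_sep, ""),
                   c = ifelse(x$is_reverse, dialect$reverse_marker, ""))
  names(df) <- c(dialect$sequence_col, dialect$proteins_col,
                 dialect$reverse_col)
  for (j in seq_len(ncol(ints)))
    df[[paste0(dialect$intensity_prefix, colnames(ints)[j])]] <-
      .fmt_num(ints[, j])
  for (j in seq_len(ncol(ints)))
    df[[paste0(dialect$msms_prefix, colnames(ints)[j])]] <- x$msms_count[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a protein table in the MaxQuant-style dialect
#' @param x A \code{ProteinQuantTable}.
#' @inheritParams write_peptide_table
#' @return Invisibly, \code{path}.
#' @export
write_protein_table <- function(x, path, dialect = mq_dialect()) {
  stopifnot(inherits(x, "ProteinQuantTable"))
  ab <- x$abundance
  ab[is.na(ab)] <- 0
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   a = x$protein_group_id,
                   b = vapply(x$entry_names, paste,
                              collapse = dialect$id_sep, ""),
                   c = ifelse(x$is_reverse, dialect$reverse_marker, ""))
  names(df) <- c(dialect$protein_id_col, dialect$entry_col,
                 dialect$reverse_col)
  for (j in seq_len(ncol(ab)))
    df[[paste0(dialect$lfq_prefix, colnames(ab)[j])]] <- .fmt_num(ab[, j])
  for (j in seq_len(ncol(ab)))
    df[[paste0(dialect$msms_prefix, colnames(ab)[j])]] <- x$msms_count[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision, locale-independent numeric formatting
.fmt_num <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                                      trim = TRUE), "")
  out
}

#' Read a study-design table
#'
#' A 3-column tab-delimited file with header
#' \code{sample_id / sample_class / group_label}. \code{sample_class} must be
#' one of \code{WTL-CTRL}, \code{LCM-CTRL}, \code{EXPERIMENTAL}; every
#' \code{EXPERIMENTAL} sample needs a non-empty biological group label
#' (e.g. \code{"ER+"} / \code{"ER-"}). An \code{order_index} recording file
#' order is attached for deterministic output ordering.
#'
#' @param path Path to the design file.
#' @return A \code{StudyDesign} data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  study_design(df$sample_id, df$sample_class, df$group_label)
}

#' Construct and validate a study design
#'
#' @param sample_id Character vector of unique sample ids.
#' @param sample_class One of \code{"WTL-CTRL"}, \code{"LCM-CTRL"},
#'   \code{"EXPERIMENTAL"} per sample.
#' @param group_label Biological group per sample; required (non-empty) for
#'   \code{EXPERIMENTAL} samples.
#' @return A data frame of class \code{StudyDesign} with columns
#'   \code{sample_id}, \code{sample_class}, \code{group_label},
#'   \code{order_index}.
#' @export
study_design <- function(sample_id, sample_class, group_label = NULL) {
  if (is.null(sample_id) || length(sample_id) == 0L)
    stop("validation error: empty study design")
  sample_id <- as.character(sample_id)
  sample_class <- as.character(sample_class)
  if (is.null(group_label)) group_label <- rep("", length(sample_id))
  group_label <- as.character(group_label)
  group_label[is.na(group_label)] <- ""
  if (anyDuplicated(sample_id))
    stop("validation error: duplicate sample_id '",
         sample_id[duplicated(sample_id)][1], "'")
  classes <- c("WTL-CTRL", "LCM-CTRL", "EXPERIMENTAL")
  bad <- setdiff(unique(sample_class), classes)
  if (length(bad))
    stop("validation error: unknown sample_class token '", bad[1], "'")
  noexp <- sample_class == "EXPERIMENTAL" & !nzchar(trimws(group_label))
  if (any(noexp))
    stop("validation error: EXPERIMENTAL sample '",
         sample_id[noexp][1], "' has no group_label")
  structure(data.frame(sample_id = sample_id, sample_class = sample_class,
                       group_label = group_label,
                       order_index = seq_along(sample_id),
                       stringsAsFactors = FALSE),
            class = c("StudyDesign", "data.frame"))
}

#' Write a study-design table
#' @param design A \code{StudyDesign}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample_id", "sample_class", "group_label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Samples of a design belonging to given classes / groups
#' @param design A \code{StudyDesign}.
#' @param sample_class Optional class filter.
#' @param group_label Optional group filter.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, sample_class = NULL, group_label = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(sample_class)) keep <- keep & design$sample_class %in% sample_class
  if (!is.null(group_label)) keep <- keep & design$group_label %in% group_label
  design$sample_id[keep]
}

#' Check sample-axis consistency between tables and design
#'
#' Raises immediately (before any computation) if a quantification table
#' references a sample absent from the design, or if peptide and protein
#' tables disagree on the sample axis. A design that covers extra samples is
#' accepted with a warning.
#'
#' @param design A \code{StudyDesign}.
#' @param peptides Optional \code{PeptideQuantTable}.
#' @param proteins Optional \code{ProteinQuantTable}.
#' @return Invisibly \code{TRUE}.
#' @export
check_sample_axis <- function(design, peptides = NULL, proteins = NULL) {
  axes <- list()
  if (!is.null(peptides)) axes$peptides <- sample_ids(peptides)
  if (!is.null(proteins)) axes$proteins <- sample_ids(proteins)
  for (nm in names(axes)) {
    missing <- setdiff(axes[[nm]], design$sample_id)
    if (length(missing))
      stop("sample-axis error: ", nm, " table references sample(s) ",
           paste(missing, collapse = ", "), " absent from the design")
  }
  if (length(axes) == 2L && !setequal(axes$peptides, axes$proteins))
    stop("sample-axis error: peptide and protein tables disagree on samples")
  if (length(axes)) {
    extra <- setdiff(design$sample_id, unique(unlist(axes)))
    if (length(extra))
      warning("design contains sample(s) with no quantification data: ",
              paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a results table deterministically
#'
#' Tab-delimited output with a fixed column order, missing values written as
#' \code{"NA"} and floating-point values at 6 significant digits. Two writes
#' of the same input are byte-identical.
#'
#' @param results A non-empty data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || !is.data.frame(results) || nrow(results) == 0L)
    stop("refusing to write empty results table")
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         vapply(out[[j]], function(v)
                           format(signif(v, 6), scientific = FALSE,
                                  trim = TRUE, digits = 15), ""))
    if (is.list(out[[j]]))
      out[[j]] <- vapply(out[[j]], paste, collapse = ";", "")
  }
  con <- file(path, open = "wb")  # fixed EOL across platforms
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}
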