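# Small in-code fixtures shared across test files.

# A 3-peptide x 3-sample toy peptide table with one decoy and one shared
# peptide; intensities chosen as powers of two for exact log2 values.
toy_peptides <- function() {
  intensity <- matrix(c(1024, 2048, 4096,
                        512, NA, 1024,
                        256, 256, 256),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(NULL, c("s1", "s2", "s3")))
  msms <- matrix(c(2L, 3L, 4L, 1L, 0L, 2L, 1L, 1L, 1L), nrow = 3,
                 byrow = TRUE, dimnames = list(NULL, c("s1", "s2", "s3")))
  peptide_quant_table(c("AAAK", "CCCK", "DDDK"),
                      list("P1", c("P1", "P2"), "P2"),
                      c(FALSE, FALSE, FALSE),
                      intensity, msms)
}

toy_design <- function() {
  study_design(c("s1", "s2", "s3"),
               rep("EXPERIMENTAL", 3),
               c("A", "A", "B"))
}

# Balanced two-group experimental design over the columns of a matrix.
exp_design <- function(sample_ids, n1) {
  study_design(sample_ids, rep("EXPERIMENTAL", length(sample_ids)),
               c(rep("A", n1), rep("B", length(sample_ids) - n1)))
}

# Protein table wrapping a log2 matrix (linear scale stored).
protein_table_from_log2 <- function(log2_mat, msms = NULL) {
  protein_quant_table(rownames(log2_mat),
                      as.list(rownames(log2_mat)),
                      rep(FALSE, nrow(log2_mat)),
                      2^log2_mat, msms)
}
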