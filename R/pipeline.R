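#' Assemble a pipeline configuration
#'
#' Collects every option of the end-to-end run in one validated list.
#' Thresholds default to the conventional discovery settings: adjusted
#' ANOVA p < 0.05 for pre-selection, t-test p < 0.05 with permutation FDR
#' <= 0.05 for both refinements, Fisher p < 0.05, top 10 peptides per
#' protein, up to 250 permutations (a 5-vs-4 design enumerates all 125
#' non-identity label splits).
#'
#' @param peptide_table,protein_table,design Paths to input files
#'   (\code{protein_table} may be \code{NULL}: the protein table is then
#'   rebuilt from the peptides by [rollup_protein_table()]).
#' @param output_dir Output directory (created if needed).
#' @param seed Mandatory integer seed.
#' @param min_obs_fraction,alpha_pre,alpha_refine,fdr,alpha_fisher
#'   Thresholds, each in (0, 1).
#' @param top_k,n_perm,min_shared Integer settings.
#' @param impute_width,impute_downshift Imputation parameters, see
#'   [imputation_spec()].
#' @param fisher_mode \code{"counts"} or \code{"detection"}.
#' @param robust Huber weighting in the ANOVA fit.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(peptide_table, protein_table = NULL,
                            design, output_dir, seed,
                            min_obs_fraction = 0.5, alpha_pre = 0.05,
                            alpha_refine = 0.05, fdr = 0.05,
                            alpha_fisher = 0.05, top_k = 10L,
                            n_perm = 250L, min_shared = 1L,
                            impute_width = 0.3, impute_downshift = 1.8,
                            fisher_mode = "counts", robust = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  for (v in c(min_obs_fraction, alpha_pre, alpha_refine, fdr, alpha_fisher))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("validation error: thresholds must lie in (0, 1)")
  structure(list(peptide_table = peptide_table,
                 protein_table = protein_table, design = design,
                 output_dir = output_dir, seed = as.integer(seed),
                 min_obs_fraction = min_obs_fraction,
                 alpha_pre = alpha_pre, alpha_refine = alpha_refine,
                 fdr = fdr, alpha_fisher = alpha_fisher,
                 top_k = as.integer(top_k), n_perm = as.integer(n_perm),
                 min_shared = as.integer(min_shared),
                 impute_width = impute_width,
                 impute_downshift = impute_downshift,
                 fisher_mode = fisher_mode, robust = robust),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Executes, in order: input reading and axis validation, peptide filtering,
#' (optional) protein rollup, the QC battery, the abundance branch, the
#' presence branch, the branch overlap, and bidirectional clustering of each
#' branch's significant proteins. Every intermediate table is written to the
#' output directory together with a manifest (configuration echo, seed,
#' package version, per-stage row counts) that suffices to re-run the
#' pipeline identically. Identical configuration and inputs produce
#' identical outputs.
#'
#' @param config A \code{PipelineConfig}.
#' @return Invisibly, a list with all in-memory results
#'   (\code{qc}, \code{abundance}, \code{presence}, \code{overlap},
#'   \code{clustering}, \code{manifest}).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  peptides <- stage("read_peptides", read_peptide_table(config$peptide_table))
  design <- stage("read_design", read_design(config$design))
  proteins <- stage("proteins", {
    if (is.null(config$protein_table))
      rollup_protein_table(peptides, min_shared = config$min_shared)
    else read_protein_table(config$protein_table)
  })
  stage("validate", check_sample_axis(design, peptides = peptides,
                                      proteins = proteins))
  filtered <- stage("filter_peptides", filter_peptides(
    peptides, design,
    filter_criteria(min_obs_fraction = config$min_obs_fraction)))
  forward <- stage("drop_reverse", drop_reverse_proteins(proteins))
  qc <- stage("qc", qc_report(peptides, proteins, design))
  write_qc_report(qc, file.path(out, "qc_report.tsv"))
  write_results_table(attr(filtered, "filter_report"),
                      file.path(out, "filter_report.tsv"))
  abundance <- stage("abundance_branch", run_abundance_branch(
    filtered, forward, design, alpha_pre = config$alpha_pre,
    alpha_refine = config$alpha_refine, fdr = config$fdr,
    top_k = config$top_k, n_perm = config$n_perm, seed = config$seed,
    robust = config$robust))
  write_results_table(abundance, file.path(out, "abundance_branch.tsv"))
  presence <- stage("presence_branch", run_presence_branch(
    forward, design,
    imputation_spec(config$impute_width, config$impute_downshift,
                    config$seed),
    alpha_fisher = config$alpha_fisher,
    alpha_refine = config$alpha_refine, fdr = config$fdr,
    n_perm = config$n_perm, seed = config$seed,
    mode = config$fisher_mode))
  write_results_table(presence, file.path(out, "presence_branch.tsv"))
  overlap <- stage("overlap", branch_overlap(abundance, presence))
  write_results_table(
    data.frame(metric = c("n_refined", "n_consolidated", "n_shared",
                          "n_concordant"),
               value = c(sum(abundance$refined), sum(presence$consolidated),
                         length(overlap$shared), overlap$n_concordant)),
    file.path(out, "branch_overlap.tsv"))
  clustering <- stage("clustering", {
    res <- list()
    exp_samples <- intersect(design_samples(design, "EXPERIMENTAL"),
                             sample_ids(forward))
    prot_log2 <- log2_transform(forward)[, exp_samples, drop = FALSE]
    sel_ab <- abundance$protein_group_id[abundance$refined]
    sel_ab <- intersect(sel_ab, rownames(prot_log2))
    if (length(sel_ab) >= 2L) {
      cb <- cluster_bidirectional(prot_log2[sel_ab, , drop = FALSE], design)
      write_cluster3(cb, file.path(out, "cluster_abundance"))
      res$abundance <- cb
    }
    sel_pr <- presence$protein_group_id[presence$consolidated]
    sel_pr <- intersect(sel_pr, rownames(prot_log2))
    if (length(sel_pr) >= 2L) {
      imp <- impute_downshifted_normal(
        prot_log2, imputation_spec(config$impute_width,
                                   config$impute_downshift, config$seed))
      cb <- cluster_bidirectional(imp[sel_pr, , drop = FALSE], design)
      write_cluster3(cb, file.path(out, "cluster_presence"))
      res$presence <- cb
    }
    res
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("lfqpipe")),
    config = unclass(config),
    stages = list(n_peptides = length(peptides$peptide_key),
                  n_peptides_filtered = length(filtered$peptide_key),
                  n_proteins = length(proteins$protein_group_id),
                  n_proteins_forward = length(forward$protein_group_id),
                  n_preselected = sum(abundance$preselected),
                  n_refined = sum(abundance$refined),
                  n_fisher_hits = sum(presence$fisher_hit),
                  n_consolidated = sum(presence$consolidated),
                  n_overlap = length(overlap$shared)))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(list(qc = qc, abundance = abundance, presence = presence,
                 overlap = overlap, clustering = clustering,
                 manifest = manifest))
}
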