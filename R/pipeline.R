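# Orchestration: scan one study end to end (read -> QC -> per-exposure gTDT
# scan -> diagnostics), meta-analyze summary files, and drive the simulator;
# the thin command-line wrapper in inst/cli/triogxe.R calls these functions.

#' Read a pipeline run configuration from YAML
#'
#' Expected top-level keys: `studies` (list of `{label, vcf, pedigree,
#' exposures}`), `exposure_names`, optional `qc` (threshold overrides),
#' `model`, `meta: {use_within_study_cov}`, `thresholds: {genomewide,
#' suggestive}`, `out_dir`, and for the simulate subcommand `simulate` (any
#' [sim_config()] argument).
#'
#' @param path YAML file.
#' @return Config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$model <- cfg$model %||% "additive"
  cfg$thresholds <- cfg$thresholds %||% list()
  cfg$thresholds$genomewide <- cfg$thresholds$genomewide %||% 5e-8
  cfg$thresholds$suggestive <- cfg$thresholds$suggestive %||% 1e-6
  if (cfg$thresholds$genomewide <= 0 || cfg$thresholds$suggestive <= 0 ||
      cfg$thresholds$genomewide >= cfg$thresholds$suggestive) {
    stop("thresholds must be positive with genomewide < suggestive")
  }
  cfg$qc <- do.call(qc_thresholds, cfg$qc %||% list())
  cfg$meta <- cfg$meta %||% list()
  cfg$meta$use_within_study_cov <- cfg$meta$use_within_study_cov %||% TRUE
  for (s in cfg$studies) {
    for (f in c("vcf", "pedigree", "exposures")) {
      if (!is.null(s[[f]]) && !file.exists(s[[f]])) {
        stop("input file does not exist: ", s[[f]])
      }
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full single-study scan
#'
#' Reads pedigree, VCF and exposure files, applies per-SNP QC, scans every
#' requested exposure with the gTDT GxE model, and writes per-exposure summary
#' statistics, the QC report, genomic-control lambdas, and QQ/Manhattan
#' tables, plus a JSON sidecar with stage counts (trios and SNPs in/out at
#' every step).
#'
#' @param vcf,pedigree,exposure_file Input paths for one study.
#' @param out_dir Output directory.
#' @param exposure_names Exposures to analyze; default: all present in the
#'   exposure file.
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param model Genetic model.
#' @param study_label Label used in file names.
#' @param genomewide,suggestive Significance flag thresholds.
#' @return Invisibly, a list with the per-exposure result data.frames, the QC
#'   report and the stage-count list.
#' @export
run_scan <- function(vcf, pedigree, exposure_file, out_dir,
                     exposure_names = NULL, thresholds = qc_thresholds(),
                     model = "additive", study_label = "study1",
                     genomewide = 5e-8, suggestive = 1e-6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trios <- read_pedigree(pedigree)
  if (nrow(trios) == 0L) stop("no complete trios in pedigree: ", pedigree)
  tm <- read_vcf_to_trios(vcf, trios)
  exposures <- read_exposure_table(exposure_file)
  if (is.null(exposure_names)) exposure_names <- unique(exposures$exposure_name)
  absent <- setdiff(exposure_names, exposures$exposure_name)
  if (length(absent)) {
    stop("exposure(s) not present in exposure table: ",
         paste(absent, collapse = ", "))
  }

  qc <- snp_qc(tm, thresholds)
  filt <- apply_qc(tm, qc)
  write_qc_report(qc, file.path(out_dir, paste0(study_label, "_qc.tsv")),
                  thresholds)

  stage <- list(study = study_label,
                trios_in = nrow(trios),
                snps_in = nrow(tm$snps),
                snps_skipped_on_read = as.list(attr(tm, "skipped")),
                snps_after_qc = nrow(filt$matrix$snps),
                qc = as.list(stats::setNames(filt$log$count, filt$log$metric)),
                exposures = list())
  results <- list()
  for (ex in exposure_names) {
    res <- scan_genome(filt$matrix, exposures, ex, model = model,
                       genomewide = genomewide, suggestive = suggestive)
    results[[ex]] <- res
    write_summary_stats(res, file.path(out_dir,
                                       paste0(study_label, "_", ex, ".tsv")))
    e <- exposures[exposures$exposure_name == ex, ]
    e <- e$exposed[match(trios$trio_id, e$trio_id)]
    l1 <- lambda_gc(res$CHISQ_1DF, 1L)
    l2 <- lambda_gc(res$CHISQ_2DF, 2L)
    stage$exposures[[ex]] <- list(
      trios_analyzed = sum(!is.na(e)),
      trios_excluded_missing_exposure = sum(is.na(e)),
      n_exposed = sum(e == 1L, na.rm = TRUE),
      lambda_1df = l1$lambda, lambda_2df = l2$lambda)
    utils::write.table(
      qq_table(res$P_1DF),
      file.path(out_dir, paste0(study_label, "_", ex, "_qq.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      manhattan_table(res, genomewide = genomewide, suggestive = suggestive),
      file.path(out_dir, paste0(study_label, "_", ex, "_manhattan.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(stage,
                       file.path(out_dir, paste0(study_label, "_stages.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, qc = qc, stages = stage))
}

#' Meta-analyze summary-statistics files from several studies
#'
#' Reads canonical summary files, harmonizes alleles, runs the scalar 1 df and
#' joint 2 df fixed-effect meta-analysis, and writes the meta table with
#' harmonization actions, lambdas and QQ/Manhattan tables.
#'
#' @param summary_files Named character vector of summary TSV paths (names =
#'   study labels).
#' @param out_dir Output directory.
#' @param use_within_study_cov Passed to [meta_joint_2df()].
#' @param label Output file prefix.
#' @param genomewide,suggestive Flag thresholds.
#' @return Invisibly, the meta result data.frame.
#' @export
run_meta <- function(summary_files, out_dir, use_within_study_cov = TRUE,
                     label = "meta", genomewide = 5e-8, suggestive = 1e-6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(summary_files))) {
    names(summary_files) <- paste0("study", seq_along(summary_files))
  }
  studies <- lapply(summary_files, read_summary_stats)
  h <- harmonize(studies)
  meta <- meta_studies(studies, use_within_study_cov = use_within_study_cov,
                       genomewide = genomewide, suggestive = suggestive)

  out <- file.path(out_dir, paste0(label, ".tsv"))
  meta_fmt <- meta
  for (j in which(vapply(meta_fmt, is.double, logical(1L)))) {
    meta_fmt[[j]] <- ifelse(is.na(meta_fmt[[j]]), "NA",
                            sprintf("%.17g", meta_fmt[[j]]))
  }
  utils::write.table(meta_fmt, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(h$actions,
                     file.path(out_dir, paste0(label, "_harmonization.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok1 <- !is.na(meta$CHISQ_1DF)
  diag <- list(lambda_1df = lambda_gc(meta$CHISQ_1DF[ok1], 1L)$lambda,
               lambda_2df = lambda_gc(meta$CHISQ_2DF, 2L)$lambda,
               n_snps = nrow(meta),
               n_studies = length(summary_files))
  jsonlite::write_json(diag, file.path(out_dir, paste0(label, "_lambda.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(qq_table(meta$P_1DF),
                     file.path(out_dir, paste0(label, "_qq.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manhattan_table(meta, genomewide = genomewide,
                                     suggestive = suggestive),
                     file.path(out_dir, paste0(label, "_manhattan.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(meta)
}

#' Simulate a study and write its files
#'
#' Convenience wrapper composing [sim_config()], [simulate_study()] and
#' [write_study_files()].
#'
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @param ... Arguments forwarded to [sim_config()].
#' @return Invisibly, the `simulated_study`.
#' @export
run_simulate <- function(out_dir, prefix = "study", ...) {
  config <- sim_config(...)
  study <- simulate_study(config)
  write_study_files(study, out_dir, prefix = prefix)
  invisible(study)
}
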