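#' Pipeline configuration
#'
#' Thresholds and switches for the end-to-end run. The simulation block is a
#' [sim_config()]; all randomness (simulation, SAM permutations, null tests)
#' derives from its `seed`.
#'
#' @param sim A [sim_config()].
#' @param q_threshold q cutoff for DE transcripts (default 0.05).
#' @param p_threshold p cutoff for DE proteins (default 0.05).
#' @param e_blast,e_annot E-value thresholds for the translated search.
#' @param sn_min,confidence_min PSM filters.
#' @param n_perm Permutations for SAM q-values.
#' @param bias_correct Apply the median labeling-bias correction.
#' @param bh_adjust Select DE proteins on BH-adjusted p-values.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            q_threshold = 0.05,
                            p_threshold = 0.05,
                            e_blast = 1e-5,
                            e_annot = 1e-8,
                            sn_min = 9,
                            confidence_min = 0.95,
                            n_perm = 200L,
                            bias_correct = FALSE,
                            bh_adjust = FALSE) {
  stopifnot(q_threshold >= 0, q_threshold <= 1,
            p_threshold >= 0, p_threshold <= 1,
            e_blast > 0, e_annot > 0, sn_min >= 0,
            confidence_min >= 0, confidence_min <= 1, n_perm >= 1)
  structure(list(sim = validate_sim_config(sim), q_threshold = q_threshold,
                 p_threshold = p_threshold, e_blast = e_blast,
                 e_annot = e_annot, sn_min = sn_min,
                 confidence_min = confidence_min, n_perm = as.integer(n_perm),
                 bias_correct = bias_correct, bh_adjust = bh_adjust),
            class = "pipeline_config")
}

#' Run the full synthetic cross-omics pipeline
#'
#' Simulate -> GPA-normalize -> SAM DE per treatment -> iTRAQ protein
#' quantitation and selection -> translated matching of DE ESTs against the
#' DE protein database -> duplicate collapse -> pair table and concordance
#' summary. When `out_dir` is given, every intermediate table is written as
#' TSV, the summary as JSON, and a run log records seed and thresholds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List: `truth`, `arrays`, `psms`, `de_mrna` (per-treatment results
#'   and the wide DE table), `quant`, `de_proteins`, `matches`, `pairs`
#'   (the `pair_table`), `summary` (per-treatment concordance + shared +
#'   Venn counts), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  stage <- "simulate"
  res <- tryCatch({
    truth <- generate_ground_truth(sim)
    arrays <- simulate_microarray(truth, sim)
    psms <- simulate_itraq(truth, sim)

    stage <- "microarray_de"
    de_runs <- list()
    for (trt in TREATMENTS) {
      de_runs[[trt]] <- microarray_de(
        arrays, trt, q_threshold = config$q_threshold,
        n_perm = config$n_perm, seed = sim$seed + 3000L + match(trt, TREATMENTS))
    }
    de_mrna_wide <- merge_de_transcripts(de_runs)

    stage <- "itraq_quant"
    quant <- quantify_proteins(psms, confidence_min = config$confidence_min,
                               sn_min = config$sn_min,
                               bh_adjust = config$bh_adjust)
    if (config$bias_correct) quant <- bias_correct(quant)
    de_prot <- select_de_proteins(quant, p_threshold = config$p_threshold,
                                  use_adjusted = config$bh_adjust)

    stage <- "seq_match"
    pairs <- empty_pair_table(de_prot)
    matches <- NULL
    if (nrow(de_prot) > 0L && nrow(de_mrna_wide) > 0L) {
      db <- build_protein_db(stats::setNames(
        truth$protein_seq[match(de_prot$protein_id, truth$gene_id)],
        de_prot$protein_id))
      est_seqs <- stats::setNames(
        truth$coding_seq[match(de_mrna_wide$est_id, truth$gene_id)],
        de_mrna_wide$est_id)
      hits <- match_ests(est_seqs, db, e_blast = config$e_blast,
                         e_annot = config$e_annot)
      if (nrow(hits) > 0L) {
        hits$fc_skf <- de_mrna_wide$fc_skf[match(hits$est_id, de_mrna_wide$est_id)]
        hits$fc_ly <- de_mrna_wide$fc_ly[match(hits$est_id, de_mrna_wide$est_id)]
        matches <- dedup_pairs(hits)
      }
      stage <- "concordance"
      pairs <- build_pair_table(de_prot, de_mrna_wide, matches)
    }
    summary <- concordance_summary(pairs)
    summary$venn <- venn_counts(de_mrna_wide, de_prot, pairs)

    list(truth = truth, arrays = arrays, psms = psms,
         de_mrna = list(runs = de_runs, wide = de_mrna_wide),
         quant = quant, de_proteins = de_prot, matches = matches,
         pairs = pairs, summary = summary, config = config)
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# DE transcripts of both treatments as one wide table: one row per EST,
# signed FC present only under treatments where the EST was selected
merge_de_transcripts <- function(de_runs) {
  ids <- unique(as.character(unlist(lapply(de_runs, function(r) r$de$gene_id))))
  wide <- data.frame(est_id = ids,
                     fc_skf = rep(NA_real_, length(ids)),
                     fc_ly = rep(NA_real_, length(ids)),
                     stringsAsFactors = FALSE)
  for (trt in names(de_runs)) {
    de <- de_runs[[trt]]$de
    wide[[paste0("fc_", tolower(trt))]][match(de$gene_id, ids)] <- de$signed_fc
  }
  wide
}

empty_pair_table <- function(de_prot) {
  build_pair_table(de_prot,
                   data.frame(est_id = character(0), fc_skf = numeric(0),
                              fc_ly = numeric(0), stringsAsFactors = FALSE),
                   NULL)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(res$arrays, file.path(out_dir, "arrays.tsv"))
  write_tsv(res$psms, file.path(out_dir, "psms.tsv"))
  for (trt in names(res$de_mrna$runs)) {
    write_tsv(res$de_mrna$runs[[trt]]$results,
              file.path(out_dir, sprintf("de_results_%s.tsv", tolower(trt))))
  }
  write_tsv(res$de_mrna$wide, file.path(out_dir, "de_transcripts.tsv"))
  write_tsv(res$quant, file.path(out_dir, "protein_quant.tsv"))
  write_tsv(res$de_proteins, file.path(out_dir, "de_proteins.tsv"))
  if (!is.null(res$matches)) {
    write_tsv(res$matches, file.path(out_dir, "matches.tsv"))
  }
  write_tsv(as.data.frame(res$pairs), file.path(out_dir, "concordance.tsv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("concord ", as.character(utils::packageVersion("concord"))),
    paste0("R ", R.version.string),
    paste0("seed ", res$config$sim$seed),
    paste0("q_threshold ", res$config$q_threshold),
    paste0("p_threshold ", res$config$p_threshold),
    paste0("e_blast ", res$config$e_blast),
    paste0("e_annot ", res$config$e_annot),
    paste0("sn_min ", res$config$sn_min),
    paste0("confidence_min ", res$config$confidence_min),
    paste0("n_perm ", res$config$n_perm))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
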