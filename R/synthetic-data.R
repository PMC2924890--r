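#' Generate the hidden ground truth of a simulated two-omics experiment
#'
#' Draws, per gene: a random coding sequence (starts ATG, no internal stop,
#' length a multiple of 3), its standard-genetic-code translation, and true
#' log2 treatment effects for mRNA and protein under each treatment (SKF =
#' D1 agonist, LY = D2 agonist). Exactly `round(n_genes * frac_de_mrna)`
#' genes get a nonzero mRNA effect per treatment (similarly for protein);
#' non-DE effects are exactly 0. Among genes DE in both layers, the protein
#' effect shares the mRNA sign with probability `concordance_rate`.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with one row per gene: `gene_id`, `coding_seq`,
#'   `protein_seq`, and per treatment `mrna_<trt>`, `prot_<trt>` (true log2
#'   effects) plus logical flags `de_mrna_<trt>`, `de_prot_<trt>`.
#' @examples
#' truth <- generate_ground_truth(sim_config(n_genes = 20, seed = 1))
#' head(truth[, c("gene_id", "mrna_skf", "prot_skf")])
#' @export
generate_ground_truth <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + .stream[["truth"]])
  n <- config$n_genes

  gene_id <- sprintf("G%04d", seq_len(n))
  coding_seq <- vapply(sample(60:200, n, replace = TRUE),
                       random_coding_sequence, character(1))
  protein_seq <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(coding_seq)))

  truth <- data.frame(gene_id = gene_id, coding_seq = coding_seq,
                      protein_seq = protein_seq, stringsAsFactors = FALSE)

  n_de_m <- round(n * config$frac_de_mrna)
  n_de_p <- round(n * config$frac_de_protein)
  eff <- config$effect_size_log2

  for (trt in TREATMENTS) {
    de_m <- sample.int(n, n_de_m)
    # protein-DE genes drawn preferentially from the mRNA-DE set so that the
    # both-layer overlap (where concordance_rate acts) is controlled
    n_from_m <- min(round(config$overlap_rate * n_de_p), length(de_m))
    pool_rest <- setdiff(seq_len(n), de_m)
    n_rest <- min(n_de_p - n_from_m, length(pool_rest))
    de_p <- c(sample(de_m, n_from_m),
              sample(pool_rest, n_rest))

    sign_m <- sample(c(-1, 1), n_de_m, replace = TRUE)
    mrna <- numeric(n)
    mrna[de_m] <- sign_m * eff

    prot <- numeric(n)
    for (g in de_p) {
      if (mrna[g] != 0) {
        same <- stats::runif(1) < config$concordance_rate
        prot[g] <- if (same) sign(mrna[g]) * eff else -sign(mrna[g]) * eff
      } else {
        prot[g] <- sample(c(-1, 1), 1) * eff
      }
    }
    key <- tolower(trt)
    truth[[paste0("mrna_", key)]] <- mrna
    truth[[paste0("prot_", key)]] <- prot
    truth[[paste0("de_mrna_", key)]] <- mrna != 0
    truth[[paste0("de_prot_", key)]] <- prot != 0
  }
  truth
}

#' Random coding sequence of a given protein length
#'
#' ATG start codon followed by `n_aa - 1` codons drawn uniformly from the 61
#' sense codons, so the translation never hits a premature stop.
#'
#' @param n_aa Protein length in residues (>= 2).
#' @return A nucleotide string of length `3 * n_aa`.
#' @keywords internal
random_coding_sequence <- function(n_aa) {
  stopifnot(n_aa >= 2)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_aa - 1L, replace = TRUE), collapse = ""))
}

#' Simulate two-channel common-reference microarray intensities
#'
#' Every array carries each gene on two duplicate spots (mirroring cDNA arrays
#' printed in duplicate). The reference channel measures the common control
#' pool; the treatment channel is offset by the gene's true mRNA effect.
#' Channel noise is multiplicative lognormal (`array_sd` on the log2 scale),
#' keeping intensities strictly positive. The last array of each treatment is
#' a dye reversal: its two channel columns are swapped, so its raw log ratio
#' is the negative of the true effect until orientation is corrected.
#'
#' @param truth Output of [generate_ground_truth()].
#' @param config The same [sim_config()].
#' @return A `data.frame` with columns `treatment`, `array_id`, `dye_swapped`,
#'   `spot_id`, `gene_id`, `ch_treat`, `ch_ref`.
#' @export
simulate_microarray <- function(truth, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + .stream[["arrays"]])
  n <- nrow(truth)
  k <- config$n_arrays_per_treatment
  base_log2 <- stats::runif(n, 8, 12)  # per-gene abundance, shared across arrays

  out <- vector("list", 2L * k)
  i <- 0L
  for (trt in TREATMENTS) {
    eff <- truth[[paste0("mrna_", tolower(trt))]]
    for (a in seq_len(k)) {
      swapped <- a == k
      # two duplicate spots per gene
      g <- rep(seq_len(n), each = 2L)
      lt <- base_log2[g] + eff[g] + stats::rnorm(2L * n, 0, config$array_sd)
      lr <- base_log2[g] + stats::rnorm(2L * n, 0, config$array_sd)
      treat_int <- 2^lt
      ref_int <- 2^lr
      i <- i + 1L
      out[[i]] <- data.frame(
        treatment = trt,
        array_id = sprintf("%s_%d", trt, a),
        dye_swapped = swapped,
        spot_id = sprintf("S%04d_%d", g, rep(1:2, times = n)),
        gene_id = truth$gene_id[g],
        ch_treat = if (swapped) ref_int else treat_int,
        ch_ref = if (swapped) treat_int else ref_int,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (no missed
#' cleavages), then retains peptides inside the configured length window.
#'
#' @param protein Amino-acid string.
#' @param min_len,max_len Length window in residues (default 6-30).
#' @return Character vector of retained peptides (possibly empty).
#' @examples
#' digest_tryptic("MAAGKLLR", min_len = 4)
#' @export
digest_tryptic <- function(protein, min_len = 6L, max_len = 30L) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n == 0L) return(character(0))
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  peps <- substring(protein, starts, ends)
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

#' Simulate iTRAQ 4-plex peptide-spectrum matches
#'
#' Peptides are tryptic fragments of the true protein sequences. Each target
#' PSM carries reporter intensities for labels 114 (control), 115 (LY) and
#' 117 (SKF) whose expected log2(115/114) and log2(117/114) equal the
#' protein's true LY and SKF effects; each channel gets independent lognormal
#' noise (`reporter_cv` on the log2 scale). Confidence scores are drawn
#' Beta(8,1) for targets and Beta(1,8) for decoys — separable but overlapping,
#' so the decoy-FDR estimator is non-trivially exercised. Decoy PSMs use
#' peptides from reversed protein sequences at the configured expected
#' fraction of all PSMs. Peptides mapping to more than one target protein are
#' flagged `is_shared`.
#'
#' @param truth Output of [generate_ground_truth()].
#' @param config The same [sim_config()].
#' @return A `data.frame` of PSMs: `psm_id`, `protein_id`, `peptide_seq`,
#'   `is_decoy`, `is_shared`, `confidence`, `sn_sum`, `i114`, `i115`, `i117`.
#' @export
simulate_itraq <- function(truth, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + .stream[["psms"]])

  peptides <- lapply(truth$protein_seq, digest_tryptic,
                     min_len = config$min_peptide_len,
                     max_len = config$max_peptide_len)
  no_pep <- lengths(peptides) == 0L
  if (any(no_pep)) {
    warning(sum(no_pep), " protein(s) yielded no peptide in the ",
            config$min_peptide_len, "-", config$max_peptide_len,
            " residue window; skipped")
  }
  keep <- which(!no_pep)
  n_spec <- stats::rpois(length(keep), config$spectra_per_protein)

  # peptide -> number of distinct target proteins, for the shared flag
  pep_tab <- table(unlist(lapply(keep, function(i) unique(peptides[[i]]))))

  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    ns <- n_spec[j]
    if (ns == 0L) next
    ly <- truth$prot_ly[i]
    skf <- truth$prot_skf[i]
    pep <- sample(peptides[[i]], ns, replace = TRUE)
    base <- stats::rnorm(ns, 10, 1)
    e <- matrix(stats::rnorm(3L * ns, 0, config$reporter_cv), ncol = 3L)
    rows[[j]] <- data.frame(
      protein_id = truth$gene_id[i],
      peptide_seq = pep,
      is_decoy = FALSE,
      is_shared = as.vector(pep_tab[pep] > 1L),
      confidence = stats::rbeta(ns, 8, 1),
      sn_sum = stats::rlnorm(ns, log(30), 0.7),
      i114 = 2^(base + e[, 1L]),
      i115 = 2^(base + ly + e[, 2L]),
      i117 = 2^(base + skf + e[, 3L]),
      stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, rows)
  n_target <- nrow(psms)

  # decoys: expected decoy_fraction of the total PSM count
  p <- config$decoy_fraction
  n_decoy <- if (p > 0 && n_target > 0L) {
    stats::rbinom(1L, size = round(n_target / (1 - p)), prob = p)
  } else 0L
  if (n_decoy > 0L) {
    rev_seqs <- vapply(truth$protein_seq[keep], function(s) {
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }, character(1))
    rev_peps <- lapply(rev_seqs, digest_tryptic,
                       min_len = config$min_peptide_len,
                       max_len = config$max_peptide_len)
    has_pep <- which(lengths(rev_peps) > 0L)
    src <- sample(has_pep, n_decoy, replace = TRUE)
    base <- stats::rnorm(n_decoy, 10, 1)
    e <- matrix(stats::rnorm(3L * n_decoy, 0, config$reporter_cv), ncol = 3L)
    decoys <- data.frame(
      protein_id = paste0("DECOY_", truth$gene_id[keep][src]),
      peptide_seq = vapply(rev_peps[src], function(p) sample(p, 1L), character(1)),
      is_decoy = TRUE,
      is_shared = FALSE,
      confidence = stats::rbeta(n_decoy, 1, 8),
      sn_sum = stats::rlnorm(n_decoy, log(30), 0.7),
      i114 = 2^(base + e[, 1L]),
      i115 = 2^(base + e[, 2L]),
      i117 = 2^(base + e[, 3L]),
      stringsAsFactors = FALSE
    )
    psms <- rbind(psms, decoys)
  }
  psms <- cbind(psm_id = sprintf("PSM%05d", seq_len(nrow(psms))), psms)
  rownames(psms) <- NULL
  attr(psms, "n_spectra_per_protein") <- stats::setNames(
    n_spec, truth$gene_id[keep])
  psms
}

#' Write all synthetic outputs of one simulated experiment
#'
#' Convenience wrapper: generates the ground truth, the microarray table and
#' the PSM table, and writes `truth.tsv`, `arrays.tsv`, `psms.tsv`,
#' `transcripts.fasta` and `proteins.fasta` into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the three in-memory tables.
#' @export
simulate_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_ground_truth(config)
  arrays <- simulate_microarray(truth, config)
  psms <- simulate_itraq(truth, config)
  write_tsv(truth, file.path(out_dir, "truth.tsv"))
  write_tsv(arrays, file.path(out_dir, "arrays.tsv"))
  write_tsv(psms, file.path(out_dir, "psms.tsv"))
  write_fasta(stats::setNames(truth$coding_seq, truth$gene_id),
              file.path(out_dir, "transcripts.fasta"), type = "DNA")
  write_fasta(stats::setNames(truth$protein_seq, truth$gene_id),
              file.path(out_dir, "proteins.fasta"), type = "AA")
  invisible(list(truth = truth, arrays = arrays, psms = psms))
}
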