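#' Filter peptide-spectrum matches before quantitation
#'
#' Retains PSMs with identification confidence at or above `confidence_min`,
#' a summed signal-to-noise strictly greater than `sn_min`, and a peptide
#' unique to one protein (shared peptides of isoforms are excluded). Row
#' order is preserved.
#'
#' @param psms PSM table (see [simulate_itraq()] for the schema).
#' @param confidence_min Minimum identification confidence (default 0.95,
#'   the 1.3 Paragon-style score).
#' @param sn_min Signal-to-noise sum threshold, strict `>` (default 9).
#' @return The retained rows of `psms`.
#' @export
filter_spectra <- function(psms, confidence_min = 0.95, sn_min = 9) {
  keep <- psms$confidence >= confidence_min &
    psms$sn_sum > sn_min &
    !psms$is_shared
  psms[keep, , drop = FALSE]
}

#' Paragon-style score from an identification confidence
#'
#' score = -log10(1 - confidence), so 95% confidence maps to 1.301 (the
#' conventional "1.3" protein-detection threshold). A confidence of exactly 1
#' is capped at `max_score`.
#'
#' @param confidence Confidence value(s) in \[0, 1\].
#' @param max_score Cap for confidence == 1 (default 10).
#' @return Numeric score(s).
#' @examples
#' score_from_confidence(0.95)  # 1.301
#' @export
score_from_confidence <- function(confidence, max_score = 10) {
  if (any(confidence < 0 | confidence > 1)) {
    stop("score_from_confidence: confidence must lie in [0, 1]", call. = FALSE)
  }
  ifelse(confidence >= 1, max_score, -log10(1 - confidence))
}

#' Reversed-database false discovery rate
#'
#' FDR at a score threshold = (number of decoy PSMs at or above it) /
#' (number of target PSMs at or above it). The estimate is not guaranteed to
#' be monotone in the threshold and no monotonization is applied.
#'
#' @param psms PSM table with `is_decoy` and `confidence` columns.
#' @param score_threshold Score cutoff (scores via [score_from_confidence()]).
#' @return List with `fdr` (NA if no target passes, flagged `undefined`),
#'   `n_decoy`, `n_target`, `undefined`.
#' @export
decoy_fdr <- function(psms, score_threshold) {
  score <- score_from_confidence(psms$confidence)
  above <- score >= score_threshold
  n_decoy <- sum(above & psms$is_decoy)
  n_target <- sum(above & !psms$is_decoy)
  if (n_target == 0L) {
    return(list(fdr = NA_real_, n_decoy = n_decoy, n_target = 0L,
                undefined = TRUE))
  }
  list(fdr = n_decoy / n_target, n_decoy = n_decoy, n_target = n_target,
       undefined = FALSE)
}

# iTRAQ label -> treatment arm
LABEL_TREATMENT <- c(`115` = "LY", `117` = "SKF")

#' Protein ratio, error factor and p-value from one protein's PSMs
#'
#' Per-PSM log2 ratio = log2(i_label / i114). The protein log ratio is the
#' arithmetic mean of PSM log ratios; ratio = 2^mean. The error factor
#' EF = 2^(t(0.975, n-1) * SE) encodes the 95% interval: the true ratio is
#' expected in \[ratio/EF, ratio*EF\] 95% of the time. The p-value is the
#' two-sided one-sample t-test of the mean log ratio against 0 (the exact
#' dual of the EF interval: p < 0.05 iff 1 lies outside it).
#'
#' @param psms Filtered PSMs of a single protein.
#' @param label Reporter label of the treatment channel: `"115"` (LY) or
#'   `"117"` (SKF).
#' @return One-row `data.frame`: `protein_id`, `treatment`, `n_spectra`,
#'   `log2_ratio`, `se`, `ratio`, `EF`, `p`, `tier` ("confident" for >= 3
#'   spectra, "reported" for 2), `flag` ("" or a reason). With fewer than 2
#'   PSMs quantitation is refused (`flag = "peptide signal was too low"`,
#'   numeric fields NA); zero scatter at n >= 2 gives EF = 1, p = 0 and
#'   `flag = "zero variance"`.
#' @examples
#' psms <- data.frame(protein_id = "P1", i114 = c(1, 1, 1),
#'                    i115 = c(2, 2, 2), i117 = c(4, 4, 4))
#' protein_ratio(psms, "117")  # ratio 4, EF 1
#' @export
protein_ratio <- function(psms, label = c("115", "117")) {
  label <- match.arg(label)
  trt <- LABEL_TREATMENT[[label]]
  pid <- unique(psms$protein_id)
  if (length(pid) != 1L) {
    stop("protein_ratio: PSMs from more than one protein", call. = FALSE)
  }
  lr <- log2(psms[[paste0("i", label)]] / psms$i114)
  n <- sum(is.finite(lr))
  lr <- lr[is.finite(lr)]
  if (n < 2L) {
    return(data.frame(protein_id = pid, treatment = trt, n_spectra = n,
                      log2_ratio = NA_real_, se = NA_real_, ratio = NA_real_,
                      EF = NA_real_, p = NA_real_, tier = NA_character_,
                      flag = "peptide signal was too low",
                      stringsAsFactors = FALSE))
  }
  m <- mean(lr)
  se <- stats::sd(lr) / sqrt(n)
  tier <- if (n >= 3L) "confident" else "reported"
  if (se == 0) {
    ef <- 1
    p <- 0
    flag <- "zero variance"
  } else {
    ef <- 2^(stats::qt(0.975, n - 1L) * se)
    p <- stats::t.test(lr, mu = 0)$p.value
    flag <- ""
  }
  data.frame(protein_id = pid, treatment = trt, n_spectra = n,
             log2_ratio = m, se = se, ratio = 2^m, EF = ef, p = p,
             tier = tier, flag = flag, stringsAsFactors = FALSE)
}

#' Quantify all proteins from a PSM table
#'
#' Applies [filter_spectra()], drops decoys, and runs [protein_ratio()] per
#' protein and treatment channel. Proteins with fewer than 2 usable PSMs are
#' reported with the refusal flag rather than silently dropped.
#'
#' @param psms Full PSM table.
#' @param confidence_min,sn_min Passed to [filter_spectra()].
#' @param bh_adjust Also compute Benjamini-Hochberg adjusted p-values per
#'   treatment in a `p_adj` column (default FALSE; the raw p is always kept).
#' @return `data.frame`, one row per protein x treatment.
#' @export
quantify_proteins <- function(psms, confidence_min = 0.95, sn_min = 9,
                              bh_adjust = FALSE) {
  flt <- filter_spectra(psms, confidence_min, sn_min)
  flt <- flt[!flt$is_decoy, , drop = FALSE]
  groups <- split(flt, flt$protein_id)
  rows <- lapply(groups, function(g) {
    rbind(protein_ratio(g, "115"), protein_ratio(g, "117"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh_adjust) {
    out$p_adj <- NA_real_
    for (trt in unique(out$treatment)) {
      sel <- out$treatment == trt & !is.na(out$p)
      out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
    }
  }
  out
}

#' Global labeling-bias correction (median centering)
#'
#' Optionally re-centers each treatment channel so the median protein log
#' ratio is 0 (median ratio 1). The p-value is re-derived from the shifted
#' mean and the stored standard error; the error factor is scatter-only and
#' unchanged.
#'
#' @param quants Output of [quantify_proteins()] (needs >= 10 quantified
#'   proteins per treatment).
#' @return `quants` with `log2_ratio`, `ratio` and `p` re-derived.
#' @export
bias_correct <- function(quants) {
  for (trt in unique(quants$treatment)) {
    sel <- quants$treatment == trt & !is.na(quants$log2_ratio)
    if (sum(sel) < 10L) {
      stop("bias_correct: need >= 10 quantified proteins per treatment",
           call. = FALSE)
    }
    med <- stats::median(quants$log2_ratio[sel])
    quants$log2_ratio[sel] <- quants$log2_ratio[sel] - med
    quants$ratio[sel] <- 2^quants$log2_ratio[sel]
    upd <- sel & quants$se > 0
    tstat <- quants$log2_ratio[upd] / quants$se[upd]
    quants$p[upd] <- 2 * stats::pt(-abs(tstat), quants$n_spectra[upd] - 1L)
  }
  quants
}

#' Select differentially expressed proteins
#'
#' A protein is selected when its p-value is strictly below `p_threshold` in
#' at least one treatment. The returned wide table carries a signed fold
#' change per treatment only where that treatment is significant (mirroring
#' how published pair tables leave non-significant cells blank).
#'
#' @param quants Output of [quantify_proteins()].
#' @param p_threshold Strict p cutoff (default 0.05).
#' @param use_adjusted Use the `p_adj` column instead of raw `p`.
#' @return `data.frame`: `protein_id`, `fc_skf`, `fc_ly`, `p_skf`, `p_ly`,
#'   `n_spectra_skf`, `n_spectra_ly`; one row per selected protein.
#' @export
select_de_proteins <- function(quants, p_threshold = 0.05,
                               use_adjusted = FALSE) {
  pcol <- if (use_adjusted) "p_adj" else "p"
  if (use_adjusted && !"p_adj" %in% names(quants)) {
    stop("select_de_proteins: run quantify_proteins(bh_adjust = TRUE) first",
         call. = FALSE)
  }
  wide <- data.frame(protein_id = unique(quants$protein_id),
                     fc_skf = NA_real_, fc_ly = NA_real_,
                     p_skf = NA_real_, p_ly = NA_real_,
                     n_spectra_skf = NA_integer_, n_spectra_ly = NA_integer_,
                     stringsAsFactors = FALSE)
  for (trt in c("SKF", "LY")) {
    sub <- quants[quants$treatment == trt, , drop = FALSE]
    i <- match(sub$protein_id, wide$protein_id)
    key <- tolower(trt)
    sig <- !is.na(sub[[pcol]]) & sub[[pcol]] < p_threshold
    wide[[paste0("p_", key)]][i] <- sub[[pcol]]
    wide[[paste0("n_spectra_", key)]][i] <- sub$n_spectra
    wide[[paste0("fc_", key)]][i[sig]] <-
      signed_fold_change(sub$ratio[sig])
  }
  keep <- (!is.na(wide$p_skf) & wide$p_skf < p_threshold) |
    (!is.na(wide$p_ly) & wide$p_ly < p_threshold)
  out <- wide[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
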