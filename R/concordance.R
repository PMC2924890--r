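#' Build the matched mRNA-protein pair table
#'
#' One row per retained (protein, EST) match after deduplication; DE proteins
#' with no matched mRNA appear with empty mRNA fields. Fold changes are
#' carried through unchanged, and a fold change referenced for an unmeasured
#' treatment stays absent — it is never imputed.
#'
#' @param de_proteins DE protein table ([select_de_proteins()] output or the
#'   packaged fixture layout): `protein_id`, `fc_skf`, `fc_ly`, optionally
#'   `protein_name`.
#' @param de_mrnas DE mRNA table: `est_id`, `fc_skf`, `fc_ly`, optionally
#'   `mrna_name`.
#' @param matches Deduplicated match list from [dedup_pairs()] (columns
#'   `est_id`, `protein_acc`, `starred`), or NULL for no matches.
#' @return `data.frame` of class `pair_table`: `protein_acc`, `protein_name`,
#'   `prot_fc_skf`, `prot_fc_ly`, `mrna_acc`, `mrna_name`, `mrna_fc_skf`,
#'   `mrna_fc_ly`, `starred`.
#' @export
build_pair_table <- function(de_proteins, de_mrnas, matches = NULL) {
  pname <- if ("protein_name" %in% names(de_proteins)) {
    de_proteins$protein_name
  } else de_proteins$protein_id
  prot <- data.frame(protein_acc = de_proteins$protein_id,
                     protein_name = pname,
                     prot_fc_skf = de_proteins$fc_skf,
                     prot_fc_ly = de_proteins$fc_ly,
                     stringsAsFactors = FALSE)
  rows <- list()
  matched_acc <- character(0)
  if (!is.null(matches) && nrow(matches) > 0L) {
    for (k in seq_len(nrow(matches))) {
      acc <- matches$protein_acc[k]
      pi <- match(acc, prot$protein_acc)
      if (is.na(pi)) next  # hit outside the DE protein list
      mi <- match(matches$est_id[k], de_mrnas$est_id)
      rows[[length(rows) + 1L]] <- data.frame(
        prot[pi, , drop = FALSE],
        mrna_acc = de_mrnas$est_id[mi],
        mrna_name = if ("mrna_name" %in% names(de_mrnas)) {
          de_mrnas$mrna_name[mi]
        } else de_mrnas$est_id[mi],
        mrna_fc_skf = de_mrnas$fc_skf[mi],
        mrna_fc_ly = de_mrnas$fc_ly[mi],
        starred = isTRUE(matches$starred[k]),
        stringsAsFactors = FALSE)
      matched_acc <- c(matched_acc, acc)
    }
  }
  unmatched <- prot[!prot$protein_acc %in% matched_acc, , drop = FALSE]
  if (nrow(unmatched) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      unmatched,
      mrna_acc = NA_character_, mrna_name = NA_character_,
      mrna_fc_skf = NA_real_, mrna_fc_ly = NA_real_, starred = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Directional agreement between matched mRNA and protein fold changes
#'
#' Counts only rows where both layers carry a fold change for the requested
#' treatment; a pair agrees when the two signed fold changes share sign.
#'
#' @param table A `pair_table` ([build_pair_table()] or
#'   [load_table1_fixture()]).
#' @param treatment `"SKF"` or `"LY"`.
#' @return List: `treatment`, `n_pairs`, `n_agree`, `agreement` (fraction;
#'   NA when `n_pairs` is 0 — undefined, not 0).
#' @export
direction_agreement <- function(table, treatment) {
  stopifnot(treatment %in% TREATMENTS)
  key <- tolower(treatment)
  p <- table[[paste0("prot_fc_", key)]]
  m <- table[[paste0("mrna_fc_", key)]]
  both <- !is.na(p) & !is.na(m)
  n_pairs <- sum(both)
  n_agree <- sum(sign(p[both]) == sign(m[both]))
  list(treatment = treatment, n_pairs = n_pairs, n_agree = n_agree,
       agreement = if (n_pairs > 0L) n_agree / n_pairs else NA_real_)
}

#' Shared-entity counts of a pair table
#'
#' @param table A `pair_table`.
#' @return List: `n_proteins_total` (distinct protein accessions) and
#'   `n_proteins_with_mrna` (distinct accessions with at least one matched
#'   mRNA under any treatment).
#' @export
shared_entity_count <- function(table) {
  list(
    n_proteins_total = length(unique(table$protein_acc)),
    n_proteins_with_mrna = length(unique(
      table$protein_acc[!is.na(table$mrna_acc)]))
  )
}

#' Venn-style counts across the two omics layers
#'
#' Every entity is counted once even when regulated by both agonists.
#'
#' @param de_mrnas DE mRNA table with `est_id`.
#' @param de_proteins DE protein table with `protein_id`.
#' @param table The pair table linking them.
#' @return List: `n_mrna`, `n_protein`, `n_overlap` (proteins with a matched
#'   mRNA; consistent with [shared_entity_count()]).
#' @export
venn_counts <- function(de_mrnas, de_proteins, table) {
  list(
    n_mrna = length(unique(de_mrnas$est_id)),
    n_protein = length(unique(de_proteins$protein_id)),
    n_overlap = shared_entity_count(table)$n_proteins_with_mrna
  )
}

#' Null test for directional agreement
#'
#' Monte-Carlo p-value for the observed agreement count under independent
#' random sign pairing: mRNA signs are redrawn i.i.d. with probability 1/2
#' and paired with the observed protein signs. The exact two-sided
#' binomial(n_pairs, 0.5) p-value is returned alongside as the closed-form
#' reference the Monte-Carlo estimate converges to.
#'
#' @param table A `pair_table`.
#' @param treatment `"SKF"` or `"LY"`.
#' @param n_perm Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @return List: `n_pairs`, `n_agree`, `p_perm`, `p_binomial` (two-sided).
#' @export
agreement_null_test <- function(table, treatment, n_perm = 10000L, seed = 1L) {
  obs <- direction_agreement(table, treatment)
  n <- obs$n_pairs
  if (n < 1L) stop("agreement_null_test: no pairs for ", treatment, call. = FALSE)
  set.seed(seed)
  null_agree <- stats::rbinom(n_perm, n, 0.5)
  dev_obs <- abs(obs$n_agree - n / 2)
  p_perm <- mean(abs(null_agree - n / 2) >= dev_obs - 1e-9)
  p_binom <- stats::binom.test(obs$n_agree, n, 0.5)$p.value
  list(n_pairs = n, n_agree = obs$n_agree, p_perm = p_perm,
       p_binomial = p_binom)
}

#' Concordance summary across treatments
#'
#' @param table A `pair_table`.
#' @param stated_n_pairs Optional named vector of externally stated pair
#'   denominators (e.g. `c(SKF = 14)`); when the recount disagrees, the
#'   summary carries a `denominator_note` surfacing both numbers instead of
#'   silently adopting either.
#' @return List keyed by treatment with `n_pairs`, `n_agree`, `agreement`,
#'   `p_binomial`, plus `shared` ([shared_entity_count()] output) and any
#'   denominator notes.
#' @export
concordance_summary <- function(table, stated_n_pairs = NULL) {
  out <- list()
  for (trt in TREATMENTS) {
    ag <- direction_agreement(table, trt)
    entry <- list(n_pairs = ag$n_pairs, n_agree = ag$n_agree,
                  agreement = ag$agreement)
    entry$p_binomial <- if (ag$n_pairs > 0L) {
      stats::binom.test(ag$n_agree, ag$n_pairs, 0.5)$p.value
    } else NA_real_
    if (!is.null(stated_n_pairs) && trt %in% names(stated_n_pairs) &&
        stated_n_pairs[[trt]] != ag$n_pairs) {
      entry$denominator_note <- sprintf(
        "recounted %d pairs with both fold changes present vs %d stated externally; agreement fraction uses the recount",
        ag$n_pairs, stated_n_pairs[[trt]])
    }
    out[[trt]] <- entry
  }
  out$shared <- shared_entity_count(table)
  out
}
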