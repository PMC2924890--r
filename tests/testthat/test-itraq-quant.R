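mk_psms <- function(conf = 0.99, sn = 20, shared = FALSE, decoy = FALSE,
                    lr115 = 0, lr117 = 0, protein = "P1") {
  n <- max(length(conf), length(sn), length(shared), length(decoy),
           length(lr115), length(lr117))
  i114 <- rep(100, n)
  data.frame(psm_id = sprintf("PSM%03d", seq_len(n)),
             protein_id = protein, peptide_seq = "PEPTIDEK",
             is_decoy = rep_len(decoy, n), is_shared = rep_len(shared, n),
             confidence = rep_len(conf, n), sn_sum = rep_len(sn, n),
             i114 = i114, i115 = i114 * 2^rep_len(lr115, n),
             i117 = i114 * 2^rep_len(lr117, n), stringsAsFactors = FALSE)
}

test_that("spectrum filter applies strict S/N > 9, confidence and shared-peptide rules", {
  psms <- mk_psms(conf = c(0.99, 0.99, 0.99, 0.90, 0.95),
                  sn = c(9.0, 9.01, 20, 20, 20),
                  shared = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  kept <- filter_spectra(psms)
  expect_identical(kept$psm_id, c("PSM002", "PSM005"))  # order preserved
  expect_identical(nrow(filter_spectra(psms[0, ])), 0L)
})

test_that("confidence maps to the Paragon-style score", {
  expect_equal(score_from_confidence(0.95), 1.301, tolerance = 1e-3)
  expect_equal(score_from_confidence(0), 0)
  expect_equal(score_from_confidence(0.99), 2)
  expect_equal(score_from_confidence(1, max_score = 8), 8)
  expect_error(score_from_confidence(1.1), "confidence")
})

test_that("decoy FDR is the decoy/target ratio above threshold", {
  psms <- mk_psms(conf = c(rep(0.999, 10), 0.999, rep(0.5, 5)),
                  decoy = c(rep(FALSE, 10), TRUE, rep(TRUE, 5)))
  r <- decoy_fdr(psms, score_threshold = 1.301)
  expect_equal(r$fdr, 0.1)
  expect_equal(r$n_decoy, 1L)
  expect_equal(r$n_target, 10L)
  none <- decoy_fdr(mk_psms(conf = rep(0.999, 4)), 1.301)
  expect_equal(none$fdr, 0)
  empty <- decoy_fdr(mk_psms(conf = rep(0.5, 4)), 1.301)
  expect_true(empty$undefined)
  expect_true(is.na(empty$fdr))
})

test_that("decoy FDR estimate tracks the realized false-target fraction", {
  set.seed(5)
  n_true <- 800; n_false_t <- 100; n_decoy <- 100
  conf <- c(rbeta(n_true, 8, 1), rbeta(n_false_t, 1, 8), rbeta(n_decoy, 1, 8))
  psms <- data.frame(
    psm_id = sprintf("PSM%04d", 1:1000), protein_id = "P",
    peptide_seq = "K", is_shared = FALSE, sn_sum = 20,
    is_decoy = c(rep(FALSE, n_true + n_false_t), rep(TRUE, n_decoy)),
    confidence = conf, i114 = 1, i115 = 1, i117 = 1,
    stringsAsFactors = FALSE)
  truth_false_target <- c(rep(FALSE, n_true), rep(TRUE, n_false_t),
                          rep(FALSE, n_decoy))
  est <- decoy_fdr(psms, 1.301)
  score <- score_from_confidence(psms$confidence)
  above_target <- score >= 1.301 & !psms$is_decoy
  realized <- sum(truth_false_target & above_target) / sum(above_target)
  halfwidth <- 1.96 * sqrt(realized * (1 - realized) / sum(above_target))
  expect_lt(abs(est$fdr - realized), halfwidth + 2 / sum(above_target))
})

test_that("protein ratio, EF and p reproduce hand computations", {
  zero_var <- mk_psms(lr117 = c(1, 1, 1))
  q <- protein_ratio(zero_var, "117")
  expect_equal(q$ratio, 2)
  expect_equal(q$EF, 1)
  expect_equal(q$p, 0)
  expect_equal(q$flag, "zero variance")
  expect_equal(q$tier, "confident")

  hand <- mk_psms(lr115 = c(0.1, 0.2, 0.3))
  h <- protein_ratio(hand, "115")
  expect_equal(h$treatment, "LY")
  expect_equal(h$log2_ratio, 0.2, tolerance = 1e-12)
  expect_equal(h$se, 0.1 / sqrt(3), tolerance = 1e-9)       # 0.0577
  expect_equal(h$ratio, 2^0.2, tolerance = 1e-9)            # 1.149
  expect_equal(h$EF, 2^(qt(0.975, 2) * 0.1 / sqrt(3)), tolerance = 1e-9)  # 1.188
  expect_equal(h$EF, 1.188, tolerance = 1e-3)
  expect_equal(h$p, t.test(c(0.1, 0.2, 0.3))$p.value, tolerance = 1e-12)

  single <- mk_psms(lr117 = 1)[1, ]
  s <- protein_ratio(single, "117")
  expect_equal(s$flag, "peptide signal was too low")
  expect_true(is.na(s$ratio))
  two <- protein_ratio(mk_psms(lr117 = c(0.2, 0.4)), "117")
  expect_equal(two$tier, "reported")
})

test_that("EF interval [ratio/EF, ratio*EF] covers the true ratio ~95%", {
  set.seed(13)
  n_prot <- 500; n_spec <- 5; noise_sd <- 0.3
  covered <- logical(n_prot)
  for (i in seq_len(n_prot)) {
    true_lr <- rnorm(1, 0, 1)
    lr <- true_lr + rnorm(n_spec, 0, noise_sd)
    q <- protein_ratio(mk_psms(lr117 = lr), "117")
    covered[i] <- 2^true_lr >= q$ratio / q$EF & 2^true_lr <= q$ratio * q$EF
  }
  halfwidth <- 1.96 * sqrt(0.95 * 0.05 / n_prot)
  expect_lt(abs(mean(covered) - 0.95), halfwidth + 1e-9)
})

test_that("label symmetry: swapping i115 and i117 swaps LY and SKF results", {
  set.seed(17)
  psms <- mk_psms(lr115 = rnorm(5, 1, 0.2), lr117 = rnorm(5, -0.5, 0.2))
  swapped <- psms
  swapped$i115 <- psms$i117
  swapped$i117 <- psms$i115
  q1 <- quantify_proteins(psms)
  q2 <- quantify_proteins(swapped)
  ly1 <- q1[q1$treatment == "LY", setdiff(names(q1), "treatment")]
  skf2 <- q2[q2$treatment == "SKF", setdiff(names(q2), "treatment")]
  rownames(ly1) <- rownames(skf2) <- NULL
  expect_equal(ly1, skf2)
})

test_that("PSM log ratios are invariant to rescaling a spectrum's intensities", {
  psms <- mk_psms(lr115 = c(0.5, 0.7, 0.3))
  scaled <- psms
  for (col in c("i114", "i115", "i117")) scaled[[col]][2] <- scaled[[col]][2] * 37
  expect_equal(quantify_proteins(psms)$ratio, quantify_proteins(scaled)$ratio,
               tolerance = 1e-12)
})

test_that("EF shrinks as spectra accumulate at fixed scatter", {
  efs <- vapply(c(2, 4, 10, 20), function(n) {
    lr <- rep(c(-0.2, 0.2), length.out = n) + 1
    protein_ratio(mk_psms(lr117 = lr), "117")$EF
  }, numeric(1))
  expect_true(all(diff(efs) < 0))
  expect_true(all(efs >= 1))
})

test_that("estimation error decreases with spectra per protein", {
  set.seed(19)
  mae <- vapply(c(2, 5, 10), function(ns) {
    errs <- replicate(300, {
      true_lr <- 1
      lr <- true_lr + rnorm(ns, 0, 0.4)
      abs(protein_ratio(mk_psms(lr117 = lr), "117")$log2_ratio - true_lr)
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("bias correction recenters the median ratio at exactly 1", {
  set.seed(2)
  psms <- do.call(rbind, lapply(1:15, function(i) {
    mk_psms(lr115 = rnorm(3, 1.5, 0.3), lr117 = rnorm(3, 0.8, 0.3),
            protein = paste0("P", i))
  }))
  q <- quantify_proteins(psms)
  qc <- bias_correct(q)
  for (trt in c("LY", "SKF")) {
    expect_equal(median(qc$ratio[qc$treatment == trt]), 1, tolerance = 1e-12)
  }
  # already-centered input passes through unchanged
  expect_equal(bias_correct(qc), qc, tolerance = 1e-12)
})

test_that("DE protein selection uses strict p < threshold per treatment", {
  q <- data.frame(protein_id = rep(c("P1", "P2", "P3"), each = 2),
                  treatment = rep(c("LY", "SKF"), 3),
                  n_spectra = 5, log2_ratio = 1, se = 0.1,
                  ratio = c(2, 2, 0.5, 0.5, 2, 2),
                  EF = 1.2,
                  p = c(0.049, 0.5, 0.05, 0.5, 0.5, 0.5),
                  tier = "confident", flag = "", stringsAsFactors = FALSE)
  de <- select_de_proteins(q, 0.05)
  expect_identical(de$protein_id, "P1")      # 0.049 in, 0.05 out (strict)
  expect_equal(de$fc_ly, 2)
  expect_true(is.na(de$fc_skf))              # non-significant cell left blank
  all_half <- q; all_half$p <- 0.5
  expect_equal(nrow(select_de_proteins(all_half)), 0L)
})

test_that("selected proteins on synthetic data are mostly true positives", {
  cfg <- sim_config(n_genes = 150, frac_de_protein = 0.3, seed = 23)
  tr <- generate_ground_truth(cfg)
  psms <- simulate_itraq(tr, cfg)
  de <- select_de_proteins(quantify_proteins(psms))
  expect_gt(nrow(de), 10)
  for (k in c("skf", "ly")) {
    called <- de$protein_id[!is.na(de[[paste0("fc_", k)]])]
    truth_eff <- tr[[paste0("prot_", k)]][match(called, tr$gene_id)]
    realized_fdp <- mean(truth_eff == 0)
    expect_lt(realized_fdp, 0.2)
  }
})
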