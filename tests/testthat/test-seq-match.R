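test_that("protein DB records residues and rejects bad input", {
  db <- build_protein_db(c(A = random_aa(100), B = random_aa(200),
                           C = random_aa(300)))
  expect_equal(db$n_residues, 600)
  expect_error(build_protein_db(character(0)), "empty")
  expect_error(build_protein_db(c(X1 = "MKT", X1 = "GDV")), "X1")
  expect_warning(db2 <- build_protein_db(c(OK = "MKTAYI", BAD = "MKZ*")),
                 "BAD")
  expect_equal(length(db2$seqs), 1L)
})

test_that("the fixture's 42 protein accessions build a 42-entry database", {
  t1 <- load_table1_fixture()
  acc <- unique(t1$protein_acc)
  set.seed(1)
  seqs <- setNames(vapply(acc, function(a) random_aa(120), character(1)), acc)
  db <- build_protein_db(seqs)  # synthetic stand-in sequences
  expect_equal(length(db$seqs), 42L)
})

test_that("six-frame translation follows the genetic code on both strands", {
  fr <- translate_six_frames("ATGGCC")
  expect_equal(fr[["+1"]], "MA")
  expect_equal(fr[["-1"]], "GH")  # revcomp GGCCAT -> GGC CAT -> G H
  fr7 <- translate_six_frames("ATGGCCA")
  expect_equal(nchar(fr7[["+2"]]), 2L)
  expect_equal(nchar(fr7[["+3"]]), 1L)
  expect_equal(translate_six_frames("TAA")[["+1"]], "*")
  expect_equal(translate_six_frames("ATN")[["+1"]], "X")
  expect_error(translate_six_frames("AT"), "codon")
})

test_that("reverse complement swaps +k and -k frames exactly", {
  set.seed(3)
  for (i in 1:5) {
    nt <- random_dna(60 + i)
    f1 <- translate_six_frames(nt)
    f2 <- translate_six_frames(revcomp_chr(nt))
    for (k in 1:3) {
      expect_identical(f1[[paste0("+", k)]], f2[[paste0("-", k)]])
      expect_identical(f1[[paste0("-", k)]], f2[[paste0("+", k)]])
    }
  }
})

test_that("self-alignment score is the BLOSUM62 diagonal sum", {
  pep <- "MKTAYIAKQR"
  res <- local_align(pep, pep)
  mat <- blosum_for_tests()
  aa <- strsplit(pep, "")[[1]]
  expect_equal(res$score, sum(mat[cbind(aa, aa)]))
  expect_equal(res$q_start, 0L)
  expect_equal(res$q_end, 10L)
})

test_that("a sequence against its reverse scores far below self-alignment", {
  # no shared 2-mer, but positive substitution scores still allow short,
  # weak local alignments; the score must stay well below the self score
  self <- local_align("MKTAYIAKQR", "MKTAYIAKQR")$score
  res <- local_align("MKTAYIAKQR", "RQKAIYATKM")
  expect_lt(res$score, self / 2)
})

test_that("alignment scores equal the exhaustive DP oracle up to length 12", {
  set.seed(7)
  for (i in 1:40) {
    a <- random_aa(sample(2:12, 1))
    b <- random_aa(sample(2:12, 1))
    expect_equal(local_align(a, b)$score, sw_oracle(a, b),
                 info = paste(a, b))
  }
  # gap-favouring related pairs
  for (i in 1:10) {
    a <- random_aa(12)
    b <- paste0(substr(a, 1, 6), random_aa(2), substr(a, 7, 12))
    expect_equal(local_align(a, b)$score, sw_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("alignments never cross stop codons", {
  pep <- "MKTAYI*AKQR"
  target <- "MKTAYIAKQR"
  res <- local_align(pep, target)
  # best segment is MKTAYI (score 33) not the full stop-crossing peptide
  expect_equal(res$score, local_align("MKTAYI", target)$score)
  expect_lte(res$q_end, 6L)
})

test_that("E-values follow the Karlin-Altschul closed form", {
  expect_equal(evalue(50, 100, 1000), 0.041 * 1e5 * exp(-13.35),
               tolerance = 1e-12)
  expect_equal(evalue(50, 100, 1000), 6.5e-3, tolerance = 0.01)
  expect_equal(evalue(50, 100, 2000) / evalue(50, 100, 1000), 2)
  expect_lt(evalue(500, 100, 1000), 1e-50)
  s <- seq(10, 100, by = 10)
  expect_true(all(diff(evalue(s, 100, 1000)) < 0))
  expect_true(all(diff(bit_score(s)) > 0))
})

test_that("a back-translated EST hits its protein at annotation grade", {
  set.seed(9)
  tr <- generate_ground_truth(sim_config(n_genes = 10, seed = 9))
  db <- build_protein_db(setNames(tr$protein_seq, tr$gene_id))
  est <- substr(tr$coding_seq[4], 1, 150)
  hits <- match_ests(c(EST1 = est), db)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$protein_acc, tr$gene_id[4])
  expect_equal(hits$frame, "+1")
  expect_lt(hits$evalue, 1e-8)
  expect_true(hits$annotation_grade)
})

test_that("random ESTs almost never hit an unrelated database", {
  set.seed(11)
  db <- build_protein_db(setNames(vapply(1:10, function(i) random_aa(150),
                                         character(1)), paste0("P", 1:10)))
  ests <- setNames(vapply(1:100, function(i) random_dna(150), character(1)),
                   paste0("E", 1:100))
  hits <- match_ests(ests, db, e_blast = 1e-5)
  expect_lte(nrow(hits), 1L)  # >= 99% of trials hit nothing
})

test_that("E-value threshold nesting holds", {
  set.seed(13)
  tr <- generate_ground_truth(sim_config(n_genes = 15, seed = 13))
  db <- build_protein_db(setNames(tr$protein_seq, tr$gene_id))
  # mix of real fragments (some short, weaker) and noise
  ests <- c(setNames(substr(tr$coding_seq[1:8], 1, c(36, 45, 60, 75, 90, 120, 150, 150)),
                     paste0("R", 1:8)),
            setNames(vapply(1:5, function(i) random_dna(120), character(1)),
                     paste0("N", 1:5)))
  h3 <- match_ests(ests, db, e_blast = 1e-3)
  h5 <- match_ests(ests, db, e_blast = 1e-5)
  h8 <- match_ests(ests, db, e_blast = 1e-8)
  expect_true(all(h8$est_id %in% h5$est_id))
  expect_true(all(h5$est_id %in% h3$est_id))
  # annotation grade is the subset at the stricter threshold
  expect_setequal(h5$est_id[h5$annotation_grade],
                  intersect(h8$est_id, h5$est_id))
})

test_that("strand symmetry: reverse-complemented ESTs keep score and E-value", {
  set.seed(15)
  tr <- generate_ground_truth(sim_config(n_genes = 8, seed = 15))
  db <- build_protein_db(setNames(tr$protein_seq, tr$gene_id))
  est <- substr(tr$coding_seq[2], 1, 120)
  fwd <- match_ests(c(E = est), db)
  rev <- match_ests(c(E = revcomp_chr(est)), db)
  expect_equal(fwd$frame, "+1")
  expect_equal(rev$frame, "-1")
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$evalue, fwd$evalue)
})

test_that("duplicate ESTs on one protein collapse by expression similarity", {
  base <- data.frame(est_id = c("E1", "E2"), protein_acc = "P1",
                     frame = "+1", score = 100, bitscore = 40,
                     evalue = 1e-10, annotation_grade = TRUE,
                     stringsAsFactors = FALSE)
  same <- base
  same$fc_skf <- c(1.6, 1.8); same$fc_ly <- NA_real_
  d1 <- dedup_pairs(same)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$est_id, "E2")  # larger |FC| kept
  expect_false(d1$starred)

  opposite <- base
  opposite$fc_skf <- c(1.6, -1.8); opposite$fc_ly <- NA_real_
  d2 <- dedup_pairs(opposite)
  expect_equal(nrow(d2), 2L)
  expect_true(all(d2$starred))

  # measured only under different treatments: distinct profiles, keep both
  disjoint <- base
  disjoint$fc_skf <- c(-1.5, NA); disjoint$fc_ly <- c(NA, 1.4)
  d3 <- dedup_pairs(disjoint)
  expect_equal(nrow(d3), 2L)
  expect_true(all(d3$starred))

  single <- same[1, ]
  d4 <- dedup_pairs(single)
  expect_equal(d4$est_id, "E1")
  expect_false(d4$starred)
})
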