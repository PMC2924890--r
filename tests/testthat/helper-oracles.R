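# Independent exhaustive-DP Smith-Waterman oracle (Gotoh, affine gaps).
# Deliberately written from the recurrences, not by calling any aligner:
# a gap of length L costs open + ext * L (the first gap residue costs
# open + ext), matching BLAST-style gap accounting.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  mat <- blosum_for_tests()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)  # best local score ending at (i, j)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in B (deletion from a)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in A
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i, j + 1L] - open - ext,
                               E[i, j + 1L] - ext)
      F[i + 1L, j + 1L] <- max(H[i + 1L, j] - open - ext,
                               F[i + 1L, j] - ext)
      diag_score <- H[i, j] + mat[A[i], B[j]]
      H[i + 1L, j + 1L] <- max(0, diag_score,
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# scoring table for the oracle, read once from the published BLOSUM62 matrix
blosum_for_tests <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp_chr <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# tiny array table builder: one treatment, k arrays, given per-gene effects,
# duplicate spots, optional noise-free channels; last array dye-swapped if asked
toy_arrays <- function(effects, k = 4, sd = 0, dye_swap_last = FALSE,
                       base = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(effects)
  rows <- list()
  for (a in seq_len(k)) {
    swapped <- dye_swap_last && a == k
    g <- rep(seq_len(n), each = 2)
    lt <- base + effects[g] + rnorm(2 * n, 0, sd)
    lr <- base + rnorm(2 * n, 0, sd)
    treat <- 2^lt; ref <- 2^lr
    rows[[a]] <- data.frame(
      treatment = "SKF", array_id = paste0("A", a), dye_swapped = swapped,
      spot_id = sprintf("S%03d_%d", g, rep(1:2, n)),
      gene_id = sprintf("G%03d", g),
      ch_treat = if (swapped) ref else treat,
      ch_ref = if (swapped) treat else ref,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
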