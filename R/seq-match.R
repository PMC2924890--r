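# BLOSUM62, loaded once from Biostrings into the package environment
.blosum_env <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_env$BLOSUM62)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = .blosum_env)
  }
  .blosum_env$BLOSUM62
}

# Karlin-Altschul constants for gapped BLOSUM62 (open 11 / extend 1)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Build a searchable protein database
#'
#' @param records Named character vector or `AAStringSet` of protein
#'   sequences (names = accessions, optionally followed by a description).
#' @return Object of class `protein_db`: list with `seqs` (an `AAStringSet`,
#'   uppercased) and `n_residues` (total residue count, the Karlin-Altschul
#'   search-space size n). Duplicate accessions are an error; records with
#'   residues outside the 20 amino acids + X are rejected with a warning.
#' @examples
#' db <- build_protein_db(c(P1 = "MKTAYIAKQR", P2 = "GDVEKGKKIF"))
#' db$n_residues
#' @export
build_protein_db <- function(records) {
  if (methods::is(records, "AAStringSet")) {
    records <- stats::setNames(as.character(records), names(records))
  }
  if (length(records) == 0L) {
    stop("build_protein_db: empty input", call. = FALSE)
  }
  acc <- vapply(strsplit(names(records), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop("build_protein_db: duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(records)
  legal <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (any(!legal)) {
    warning("rejecting ", sum(!legal), " record(s) with illegal residues: ",
            paste(acc[!legal], collapse = ", "))
    seqs <- seqs[legal]
    acc <- acc[legal]
  }
  if (length(seqs) == 0L) {
    stop("build_protein_db: no legal records left", call. = FALSE)
  }
  set <- Biostrings::AAStringSet(stats::setNames(seqs, acc))
  structure(list(seqs = set, n_residues = sum(Biostrings::width(set))),
            class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  cat("<protein_db> ", length(x$seqs), " entries, ",
      x$n_residues, " residues\n", sep = "")
  invisible(x)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Frames +1..+3 read the forward strand at offsets 0..2; frames -1..-3 read
#' the reverse complement likewise. Standard genetic code; stop codons are
#' emitted as `*`; codons containing N translate to X.
#'
#' @param nt Nucleotide string over A/C/G/T/N, length >= 3.
#' @return Named character vector of the six translations
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @examples
#' translate_six_frames("ATGGCC")[["+1"]]  # "MA"
#' @export
translate_six_frames <- function(nt) {
  nt <- toupper(as.character(nt))
  if (nchar(nt) < 3L) {
    stop("translate_six_frames: sequence shorter than one codon", call. = FALSE)
  }
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = n),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  c(`+1` = one(fwd, 0L), `+2` = one(fwd, 1L), `+3` = one(fwd, 2L),
    `-1` = one(rev, 0L), `-2` = one(rev, 1L), `-3` = one(rev, 2L))
}

#' Smith-Waterman local alignment score (BLOSUM62, affine gaps)
#'
#' Local alignment with BLOSUM62 and BLAST-default affine gap costs (open 11,
#' extend 1; a gap of length L costs 11 + L). Query segments are split at
#' stop codons (`*`) so an alignment never crosses one; the best-scoring
#' segment wins, ties broken by the lowest query start, then target start.
#'
#' @param query,target Amino-acid strings (query may contain `*`).
#' @return List: `score` (raw, substitution-matrix units), `q_start`,
#'   `q_end`, `t_start`, `t_end` (0-based, half-open, on the full query).
#'   Score 0 with empty coordinates when nothing aligns.
#' @export
local_align <- function(query, target) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  segs <- stop_free_segments(query)
  best <- list(score = 0, q_start = NA_integer_, q_end = NA_integer_,
               t_start = NA_integer_, t_end = NA_integer_)
  for (k in seq_len(nrow(segs))) {
    seg <- substr(query, segs$start[k], segs$end[k])
    if (nchar(seg) == 0L) next
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(seg),
      subject = Biostrings::AAString(target),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(pa)
    if (sc > best$score) {
      qs <- Biostrings::start(Biostrings::pattern(pa)) + segs$start[k] - 1L
      qe <- Biostrings::end(Biostrings::pattern(pa)) + segs$start[k] - 1L
      best <- list(score = sc,
                   q_start = qs - 1L, q_end = qe,           # 0-based half-open
                   t_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
                   t_end = Biostrings::end(Biostrings::subject(pa)))
    }
  }
  best
}

# six-frame translation of many sequences with a single translate() call;
# returns a list (per sequence) of named 6-frame character vectors
six_frame_batch <- function(ests) {
  n <- length(ests)
  fwd <- Biostrings::DNAStringSet(unname(ests))
  rev <- Biostrings::reverseComplement(fwd)
  subs <- vector("list", 6L)
  k <- 0L
  for (strand in list(fwd, rev)) {
    for (off in 0:2) {
      k <- k + 1L
      w <- Biostrings::width(strand) - off
      w <- pmax(w - w %% 3L, 0L)
      subs[[k]] <- Biostrings::subseq(strand, start = off + 1L, width = w)
    }
  }
  all_subs <- do.call(c, subs)
  peps <- as.character(Biostrings::translate(all_subs, if.fuzzy.codon = "X",
                                             no.init.codon = TRUE))
  lapply(seq_len(n), function(i) {
    stats::setNames(peps[i + n * 0:5],
                    c("+1", "+2", "+3", "-1", "-2", "-3"))
  })
}

# 1-based inclusive coordinates of the maximal stop-free runs of a peptide
stop_free_segments <- function(aa) {
  r <- rle(strsplit(aa, "")[[1]] == "*")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Karlin-Altschul E-value
#'
#' E = K * m * n * exp(-lambda * S) with the published gapped-BLOSUM62
#' constants lambda = 0.267, K = 0.041 (no edge-effect length correction).
#'
#' @param raw_score Raw alignment score S.
#' @param m Query length (residues of the translated frame).
#' @param n Database size in residues.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Expected number of chance hits at score >= S.
#' @examples
#' evalue(50, 100, 1000)  # ~6.5e-3
#' @export
evalue <- function(raw_score, m, n, lambda = KA_LAMBDA, K = KA_K) {
  stopifnot(m >= 1, n >= 1)
  K * m * n * exp(-lambda * raw_score)
}

#' Bit score from a raw score
#'
#' @inheritParams evalue
#' @return Bit score (lambda * S - ln K) / ln 2; increases iff S does.
#' @export
bit_score <- function(raw_score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Match ESTs to a protein database by translated local alignment
#'
#' Each EST is translated in six frames and every frame is aligned against
#' every database protein. The best hit per EST (highest bit score, ties by
#' accession, then frame) is retained when its E-value is at most `e_blast`;
#' hits with E at most `e_annot` are additionally flagged annotation-grade.
#'
#' @param ests Named character vector or `DNAStringSet` of EST nucleotide
#'   sequences.
#' @param db A [build_protein_db()] object.
#' @param e_blast E-value threshold for reporting a hit (default 1e-5).
#' @param e_annot Stricter threshold for the annotation-grade flag
#'   (default 1e-8).
#' @return `data.frame`: `est_id`, `protein_acc`, `frame`, `score`,
#'   `bitscore`, `evalue`, `annotation_grade`. ESTs without a qualifying hit
#'   are absent.
#' @export
match_ests <- function(ests, db, e_blast = 1e-5, e_annot = 1e-8,
                       chunk_size = 100000L) {
  stopifnot(inherits(db, "protein_db"))
  if (methods::is(ests, "DNAStringSet")) {
    ests <- stats::setNames(as.character(ests), names(ests))
  }
  acc <- names(db$seqs)
  n_db <- length(acc)
  frames_order <- c("+1", "+2", "+3", "-1", "-2", "-3")

  # translate all frames of all ESTs in one pass (one genetic-code setup),
  # then enumerate every stop-free segment of every frame
  frame_tab <- six_frame_batch(ests)
  seg_est <- integer(0); seg_frame <- character(0)
  seg_str <- character(0); seg_m <- integer(0)
  for (i in seq_along(ests)) {
    frames <- frame_tab[[i]]
    for (fr in frames_order) {
      pep <- frames[[fr]]
      if (nchar(pep) < 1L) next
      segs <- stop_free_segments(pep)
      ss <- substring(pep, segs$start, segs$end)
      ss <- ss[nchar(ss) > 0L]
      if (length(ss) == 0L) next
      seg_est <- c(seg_est, rep(i, length(ss)))
      seg_frame <- c(seg_frame, rep(fr, length(ss)))
      seg_str <- c(seg_str, ss)
      seg_m <- c(seg_m, rep(nchar(pep), length(ss)))
    }
  }
  empty <- data.frame(est_id = character(0), protein_acc = character(0),
                      frame = character(0), score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      annotation_grade = logical(0), stringsAsFactors = FALSE)
  if (length(seg_str) == 0L) return(empty)

  # all (segment, protein) pairs, scored in chunked batch alignments
  seg_set <- Biostrings::AAStringSet(seg_str)
  pair_seg <- rep(seq_along(seg_str), each = n_db)
  pair_db <- rep(seq_len(n_db), times = length(seg_str))
  scores <- numeric(length(pair_seg))
  for (start in seq(1L, length(pair_seg), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, length(pair_seg))
    scores[idx] <- Biostrings::pairwiseAlignment(
      pattern = seg_set[pair_seg[idx]], subject = db$seqs[pair_db[idx]],
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }

  # reduce: per (est, frame, protein) the max over segments
  key <- data.frame(est = seg_est[pair_seg], frame = seg_frame[pair_seg],
                    m = seg_m[pair_seg], prot = pair_db, score = scores,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(score ~ est + frame + m + prot, data = key, FUN = max)

  rows <- lapply(split(agg, agg$est), function(g) {
    g$bitscore <- bit_score(g$score)
    g$evalue <- evalue(g$score, m = g$m, n = db$n_residues)
    # best hit: highest bit score; ties by accession, then frame order
    g <- g[order(-g$bitscore, acc[g$prot], match(g$frame, frames_order)), ]
    g[1L, , drop = FALSE]
  })
  best <- do.call(rbind, rows)
  best <- best[best$evalue <= e_blast, , drop = FALSE]
  if (nrow(best) == 0L) return(empty)
  out <- data.frame(est_id = names(ests)[best$est],
                    protein_acc = acc[best$prot],
                    frame = best$frame, score = best$score,
                    bitscore = best$bitscore, evalue = best$evalue,
                    annotation_grade = best$evalue <= e_annot,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$est_id, names(ests))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse multiple ESTs matching one protein
#'
#' When two or more ESTs hit the same protein, their expression profiles are
#' compared: if the signed fold changes agree in sign in every treatment
#' where both ESTs are measured (and they share at least one measured
#' treatment), the expression is "similar" and only the EST with the largest
#' absolute fold change is kept. If any treatment shows opposite signs — or
#' the ESTs are measured only under different treatments — all are kept and
#' flagged starred, since they may correspond to separate genes.
#'
#' @param hits Output of [match_ests()] augmented with the matching EST's
#'   signed fold changes in columns `fc_skf` and `fc_ly` (NA = not measured).
#' @return `hits` rows after deduplication, with a logical `starred` column.
#' @export
dedup_pairs <- function(hits) {
  stopifnot(all(c("fc_skf", "fc_ly") %in% names(hits)))
  if (nrow(hits) == 0L) {
    hits$starred <- logical(0)
    return(hits)
  }
  out <- lapply(split(hits, hits$protein_acc), function(g) {
    g$starred <- FALSE
    if (nrow(g) == 1L) return(g)
    fcs <- as.matrix(g[, c("fc_skf", "fc_ly")])
    similar <- TRUE
    for (a in seq_len(nrow(g) - 1L)) {
      for (b in seq((a + 1L), nrow(g))) {
        both <- !is.na(fcs[a, ]) & !is.na(fcs[b, ])
        if (!any(both)) {
          similar <- FALSE  # disjoint treatments: distinct profiles
        } else if (any(sign(fcs[a, both]) != sign(fcs[b, both]))) {
          similar <- FALSE
        }
      }
    }
    if (similar) {
      mx <- apply(abs(fcs), 1L, max, na.rm = TRUE)
      g[which.max(mx), , drop = FALSE]
    } else {
      g$starred <- TRUE
      g
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
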