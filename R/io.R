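# md5 of the packaged pair-table fixture; guards against silent edits
TABLE1_MD5 <- "f8af3a15c8cd46d2ff445c75009fa1d2"

#' Read a FASTA file
#'
#' Headers are parsed as "accession description"; the returned names keep the
#' full header. Empty files and duplicate accessions are errors.
#'
#' @param path FASTA file path.
#' @param type `"DNA"` or `"AA"`.
#' @return A `DNAStringSet` or `AAStringSet`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- switch(type,
                DNA = Biostrings::readDNAStringSet(path),
                AA = Biostrings::readAAStringSet(path))
  if (length(set) == 0L) {
    stop("read_fasta: no records in ", path, call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("read_fasta: record with empty sequence in ", path, call. = FALSE)
  }
  acc <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop("read_fasta: duplicate id(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  set
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector or XStringSet.
#' @param path Output path.
#' @param type `"DNA"` or `"AA"` (ignored when `records` is an XStringSet).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, type = c("DNA", "AA")) {
  if (is.character(records)) {
    type <- match.arg(type)
    records <- switch(type,
                      DNA = Biostrings::DNAStringSet(records),
                      AA = Biostrings::AAStringSet(records))
  }
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

# TSV conventions shared by every table the pipeline writes: header row,
# tab separator, no quoting of numbers, NA as empty cell
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Load the packaged mRNA-protein pair-table fixture
#'
#' A literal transcription of the published pair table for the two dopamine
#' agonists (42 differentially expressed proteins, 21 of them with a matched
#' differentially expressed mRNA; starred rows mark duplicate ESTs kept for
#' showing distinct expression profiles). Blank cells parse as absent values,
#' never 0. The file's md5 checksum is verified on load.
#'
#' @param path Override the packaged fixture location (testing only).
#' @return A `pair_table` data.frame (see [build_pair_table()]).
#' @examples
#' t1 <- load_table1_fixture()
#' direction_agreement(t1, "LY")
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_pairs.tsv", package = "concord",
                        mustWork = TRUE)
  }
  if (unname(tools::md5sum(path)) != TABLE1_MD5) {
    stop("load_table1_fixture: checksum mismatch for ", path, call. = FALSE)
  }
  t1 <- read_tsv(path)
  t1$starred <- as.logical(t1$starred)
  num <- c("prot_fc_skf", "prot_fc_ly", "mrna_fc_skf", "mrna_fc_ly")
  for (cl in num) t1[[cl]] <- as.numeric(t1[[cl]])
  class(t1) <- c("pair_table", "data.frame")
  t1
}
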