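#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-contig, arbitrarily line-wrapped) FASTA file,
#' case-folds to uppercase, and validates the alphabet. Contig order is
#' preserved; contig names are the first whitespace-delimited token of each
#' header.
#'
#' @param path Path to a FASTA file.
#' @return A `reference_genome` object.
#' @export
load_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    stop("no sequences in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  reference_genome(stats::setNames(toupper(as.character(set)), nm))
}

#' Construct a reference genome from in-memory sequences
#'
#' @param seqs Named character vector of contig sequences (A/C/G/T/N; lower
#'   case is folded to upper).
#' @return An object of class `reference_genome`: a list with `seq` (named
#'   uppercase character vector) and `total_length`.
#' @export
reference_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all contigs must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig name: ",
         names(seqs)[anyDuplicated(names(seqs))])
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad != -1L)
      stop(sprintf("illegal character in contig '%s' at position %d",
                   names(seqs)[i], as.integer(bad)))
  }
  structure(list(seq = seqs, total_length = sum(nchar(seqs))),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("Reference genome: %d contig(s), %s bases\n",
              length(x$seq), format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Build an exact-occurrence index over a reference
#'
#' The index supports exact, full-length counting of arbitrary queries over
#' both strands of every contig, used as the genomic-redundancy screen for
#' arm candidates: a candidate matching more than one genomic placement is
#' redundant. Matching is exact (no mismatches), implementing the criterion
#' of perfect multi-alignment directly; genomic N never matches any query
#' base and queries must be N-free.
#'
#' @param genome A [reference_genome()].
#' @param anchor_k Minimum query length the index accepts (1-21; default 12).
#' @return An object of class `occurrence_index`.
#' @export
build_index <- function(genome, anchor_k = 12L) {
  stopifnot(inherits(genome, "reference_genome"))
  anchor_k <- as.integer(anchor_k)
  if (is.na(anchor_k) || anchor_k < 1L || anchor_k > 21L)
    stop("anchor_k must be in [1, 21]")
  structure(list(
    subject = Biostrings::DNAStringSet(genome$seq),
    anchor_k = anchor_k
  ), class = "occurrence_index")
}

#' Count perfect genomic occurrences of a query on both strands
#'
#' Returns the number of perfect, full-length placements of `query` over both
#' strands of all contigs: Watson-strand matches of the query plus
#' Watson-strand matches of its reverse complement (= Crick-strand matches).
#' Overlapping placements count individually. For a palindromic query the two
#' orientations describe the same duplex placement and each genomic site is
#' counted once. Strand-symmetric: `count_occurrences(ix, q) ==
#' count_occurrences(ix, revcomp(q))`.
#'
#' @param index An [build_index()] result.
#' @param query A/C/G/T string, length >= `anchor_k`.
#' @return Integer occurrence count (>= 0).
#' @export
count_occurrences <- function(index, query) {
  stopifnot(inherits(index, "occurrence_index"))
  .check_dna(query, allow_n = FALSE, allow_empty = FALSE)
  if (nchar(query) < index$anchor_k)
    stop("query shorter than anchor_k (", index$anchor_k, ")")
  q <- Biostrings::DNAString(query)
  n <- sum(Biostrings::vcountPattern(q, index$subject))
  rc <- Biostrings::reverseComplement(q)
  if (as.character(rc) != query)
    n <- n + sum(Biostrings::vcountPattern(rc, index$subject))
  as.integer(n)
}

# Watson-strand substring in 0-based half-open coordinates; internal helper
# used across the designer and simulator.
.ref_substr <- function(genome, contig, start, end) {
  s <- genome$seq[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  if (start < 0L || end > nchar(s) || start > end)
    stop(sprintf("span [%d,%d) out of bounds for contig %s (len %d)",
                 start, end, contig, nchar(s)))
  substr(s, start + 1L, end)
}
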