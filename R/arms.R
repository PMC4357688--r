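#' Enumerate annealing-arm candidates for one side of a tile
#'
#' For each (length l, shift s) combination — 5 x 5 = 25 by default — the
#' arm's inner edge is displaced d = (l_max - l) + s bases outward from the
#' tile boundary and the arm extends a further l bases outward, so the
#' attainable gap-fill lengths are `tile_length + d_ext + d_lig` (100-116 with
#' default geometry). The extension arm flanks the tile on the left (lower
#' genomic coordinate on the Watson strand), the ligation arm on the right;
#' sequence, melting temperature and GC are computed on the Watson strand.
#' Candidates that would leave the contig, or contain N (melting temperature
#' undefined), are dropped and the result carries attribute `incomplete =
#' TRUE`.
#'
#' @param tile One-row tile data.frame (as produced by [tile_targets()]).
#' @param side `"ext"` (extension, left flank) or `"lig"` (ligation, right).
#' @param genome A [reference_genome()].
#' @param params A [design_params()].
#' @return Data.frame of candidates: `side`, `l`, `s`, `d`, `start`, `end`
#'   (0-based half-open genomic span), `seq`, `tm`, `gc`.
#' @export
enumerate_arm_candidates <- function(tile, side = c("ext", "lig"),
                                     genome, params = design_params()) {
  side <- match.arg(side)
  l_max <- max(params$arm_lengths)
  grid <- expand.grid(l = params$arm_lengths, s = params$shifts,
                      KEEP.OUT.ATTRS = FALSE)
  grid$d <- (l_max - grid$l) + grid$s
  if (side == "ext") {
    grid$start <- tile$start - grid$d - grid$l
    grid$end <- tile$start - grid$d
  } else {
    grid$start <- tile$end + grid$d
    grid$end <- tile$end + grid$d + grid$l
  }
  clen <- nchar(genome$seq[[tile$contig]])
  ok <- grid$start >= 0L & grid$end <= clen
  cands <- grid[ok, , drop = FALSE]
  cands$seq <- vapply(seq_len(nrow(cands)), function(i)
    .ref_substr(genome, tile$contig, cands$start[i], cands$end[i]),
    character(1))
  has_n <- grepl("N", cands$seq, fixed = TRUE)
  cands <- cands[!has_n, , drop = FALSE]
  cands$tm <- vapply(cands$seq, melting_temp, numeric(1),
                     model = params$thermo, USE.NAMES = FALSE)
  cands$gc <- vapply(cands$seq, gc_percent, numeric(1), USE.NAMES = FALSE)
  cands <- cbind(side = side, cands, stringsAsFactors = FALSE)
  rownames(cands) <- NULL
  attr(cands, "incomplete") <- nrow(cands) < nrow(grid)
  cands
}

#' Screen arm candidates against the exclusion criteria
#'
#' A candidate is excluded if its sequence contains the EarI recognition site
#' on either strand, occurs more than once in the genome (perfect full-length
#' match on either strand), contains a homopolymer run longer than
#' `max_homopolymer`, or has GC content outside `(gc_min, gc_max)`. Every
#' candidate carries all applicable flags; exclusion counts attribute each
#' excluded candidate to its first failing criterion in the order
#' earI, redundancy, homopolymer, gc.
#'
#' @param cands Candidates from [enumerate_arm_candidates()].
#' @param index An [build_index()] over the same genome.
#' @param params A [design_params()].
#' @return List with `survivors` (data.frame), `flagged` (all candidates with
#'   flag columns and `first_fail`), and `counts` (named integer vector over
#'   the four exclusion categories).
#' @export
filter_candidates <- function(cands, index, params = design_params()) {
  n <- nrow(cands)
  cands$flag_earI <- vapply(cands$seq, function(s)
    nrow(find_motif_both_strands(s, params$earI_motif)) > 0L, logical(1),
    USE.NAMES = FALSE)
  cands$flag_redundant <- vapply(cands$seq, function(s)
    count_occurrences(index, s) > 1L, logical(1), USE.NAMES = FALSE)
  cands$flag_homopolymer <- vapply(cands$seq, function(s)
    max_homopolymer_run(s) > params$max_homopolymer, logical(1),
    USE.NAMES = FALSE)
  cands$flag_gc <- cands$gc < params$gc_min | cands$gc > params$gc_max
  flags <- cbind(earI = cands$flag_earI, redundancy = cands$flag_redundant,
                 homopolymer = cands$flag_homopolymer, gc = cands$flag_gc)
  first <- apply(flags, 1L, function(f)
    if (any(f)) colnames(flags)[which(f)[1]] else NA_character_)
  cands$first_fail <- if (n) first else character(0)
  counts <- vapply(c("earI", "redundancy", "homopolymer", "gc"),
                   function(k) sum(cands$first_fail == k, na.rm = TRUE),
                   integer(1))
  list(survivors = cands[is.na(cands$first_fail), , drop = FALSE],
       flagged = cands,
       counts = counts)
}

#' Select the best surviving arm candidate
#'
#' Lexicographic rule: smallest |Tm - tm_opt|, ties broken by smallest
#' |GC - gc_opt|, then longer arm, then smaller shift — fully deterministic.
#'
#' @param survivors Non-empty survivor data.frame from [filter_candidates()].
#' @param params A [design_params()].
#' @return The chosen one-row candidate.
#' @export
select_best_candidate <- function(survivors, params = design_params()) {
  if (is.null(survivors) || nrow(survivors) == 0L)
    stop("no surviving arm candidates")
  ord <- order(abs(survivors$tm - params$tm_opt),
               abs(survivors$gc - params$gc_opt),
               -survivors$l,
               survivors$s)
  survivors[ord[1L], , drop = FALSE]
}
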