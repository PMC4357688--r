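#' Read target regions from a BED file
#'
#' @param path BED file of target regions.
#' @return A data.frame with `contig`, `start`, `end` (0-based half-open) and
#'   `name` columns.
#' @export
read_targets_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("region", seq_along(gr))
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm,
             stringsAsFactors = FALSE)
}

#' Tile target regions at 2x density
#'
#' Each region is cut into `tile_length` tiles stepping by
#' `tile_length - tile_overlap` (100/50 by default, so most interior bases are
#' covered by two tiles). The final tile is anchored to the region end, so its
#' overlap with the previous tile may exceed the nominal overlap. Regions
#' shorter than one tile yield a single tile centered on the region, expanded
#' symmetrically into flanking sequence (short exons keep their splice
#' junctions covered). When `genome` is supplied, regions whose tiles (plus
#' the arm-candidate flank) would leave the contig are reported as failed
#' rather than raising an error.
#'
#' @param regions Data.frame with `contig`, `start`, `end` (0-based half-open)
#'   and optionally `name`; or a `GRanges`.
#' @param params A [design_params()].
#' @param genome Optional [reference_genome()] for bounds checking.
#' @return A data.frame of tiles (`contig`, `start`, `end`, `region`,
#'   `tile_index`), with failed regions (if any) in `attr(, "failed")`.
#' @export
tile_targets <- function(regions, params = design_params(), genome = NULL) {
  if (inherits(regions, "GRanges")) {
    regions <- data.frame(
      contig = as.character(GenomicRanges::seqnames(regions)),
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  if (is.null(regions$name))
    regions$name <- paste0("region", seq_len(nrow(regions)))
  L <- params$tile_length
  step <- L - params$tile_overlap
  flank <- (max(params$arm_lengths) - min(params$arm_lengths)) +
    max(params$shifts) + max(params$arm_lengths)
  out <- vector("list", nrow(regions))
  failed <- character(0)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    len <- r$end - r$start
    if (len <= 0L) { failed <- c(failed, r$name); next }
    if (len < L) {
      center <- (r$start + r$end) %/% 2L
      starts <- center - L %/% 2L
    } else {
      starts <- seq.int(r$start, r$end - L, by = step)
      if (utils::tail(starts, 1L) + L < r$end)
        starts <- c(starts, r$end - L)
    }
    if (!is.null(genome)) {
      clen <- nchar(genome$seq[[r$contig]])
      if (is.null(clen) ||
          min(starts) - flank < 0L || max(starts) + L + flank > clen) {
        failed <- c(failed, r$name)
        next
      }
    }
    out[[i]] <- data.frame(contig = r$contig,
                           start = as.integer(starts),
                           end = as.integer(starts + L),
                           region = r$name,
                           tile_index = seq_along(starts),
                           stringsAsFactors = FALSE)
  }
  tiles <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(tiles))
    tiles <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), region = character(0),
                        tile_index = integer(0), stringsAsFactors = FALSE)
  attr(tiles, "failed") <- failed
  tiles
}
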