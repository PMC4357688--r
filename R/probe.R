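#' Design one probe for a target tile
#'
#' Runs enumerate -> filter -> select independently for the extension and
#' ligation sides. The gap-fill span is the tile expanded by the chosen
#' displacements d_ext and d_lig, so its length is
#' `tile_length + d_ext + d_lig` (100-116 by default). If either side has no
#' surviving candidate the probe fails with the category that eliminated most
#' candidates on the failing side(s) (ties resolved in the order earI,
#' redundancy, homopolymer, gc).
#'
#' @param tile One-row tile data.frame.
#' @param genome A [reference_genome()].
#' @param index An [build_index()] over `genome`.
#' @param params A [design_params()].
#' @return A list of class `mip_probe` with `status` "designed" (fields
#'   `ext`, `lig`, `gapfill_start`, `gapfill_end`, `gapfill_len`) or "failed"
#'   (field `category`).
#' @export
design_probe <- function(tile, genome, index, params = design_params()) {
  sides <- lapply(c("ext", "lig"), function(sd) {
    cands <- enumerate_arm_candidates(tile, sd, genome, params)
    filter_candidates(cands, index, params)
  })
  names(sides) <- c("ext", "lig")
  empty <- vapply(sides, function(x) nrow(x$survivors) == 0L, logical(1))
  if (any(empty)) {
    counts <- Reduce(`+`, lapply(sides[empty], `[[`, "counts"))
    cat_order <- c("earI", "redundancy", "homopolymer", "gc")
    category <- cat_order[which.max(counts[cat_order])]
    return(structure(list(status = "failed", tile = tile,
                          category = category), class = "mip_probe"))
  }
  ext <- select_best_candidate(sides$ext$survivors, params)
  lig <- select_best_candidate(sides$lig$survivors, params)
  gf_start <- tile$start - ext$d
  gf_end <- tile$end + lig$d
  structure(list(status = "designed", tile = tile, ext = ext, lig = lig,
                 gapfill_start = gf_start, gapfill_end = gf_end,
                 gapfill_len = gf_end - gf_start),
            class = "mip_probe")
}

#' Simulate EarI digestion of a duplex oligo (top strand)
#'
#' EarI (CTCTTC, cutting 1 nt downstream on the recognition strand and 4 nt
#' on the complement) is modelled on the top strand: each CTCTTC at 0-based
#' position p cuts the top strand after p + 6 + 1 bases; each bottom-strand
#' site (GAAGAG on top at position p) cuts the top strand 4 nt before it,
#' i.e. after p - 4 bases. Fragments between consecutive cuts are returned.
#'
#' @param top Top-strand sequence of the duplex.
#' @param motif Recognition site (default "CTCTTC").
#' @return Character vector of top-strand fragments, 5' to 3'.
#' @export
digest_earI <- function(top, motif = "CTCTTC") {
  hits <- find_motif_both_strands(top, motif)
  cuts <- integer(0)
  plus <- hits$pos[hits$strand == "+"]
  minus <- hits$pos[hits$strand == "-"]
  if (length(plus)) cuts <- c(cuts, plus + nchar(motif) + 1L)
  if (length(minus)) cuts <- c(cuts, minus - 4L)
  n <- nchar(top)
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  substring(top, utils::head(bounds, -1L) + 1L, utils::tail(bounds, -1L))
}

#' Assemble the microarray precursor oligo for a designed probe
#'
#' Precursor top strand, 5' to 3': AmpF primer region, outer spacer, EarI
#' cassette oriented to cut toward the MIP (top-strand cut lands exactly at
#' the MIP 5' terminus), the MIP itself (5' ligation arm, constant backbone,
#' 10-nt random barcode adjacent to the 3' extension arm), the mirrored EarI
#' cassette, outer spacer and AmpR primer region. The barcode is drawn
#' i.i.d. uniform over A/C/G/T from the current RNG stream. Assembly is
#' validated by simulated EarI digestion: the released middle fragment must
#' equal the MIP top strand exactly and the precursor must carry exactly one
#' recognition placement per strand. If a junction (or a barcode draw)
#' creates a spurious EarI motif, alternative spacers and fresh barcodes are
#' tried; exhaustion raises an error.
#'
#' @param probe A designed `mip_probe` from [design_probe()].
#' @param params A [design_params()].
#' @return List with `barcode`, `mip` (probe top strand) and `precursor`.
#' @export
assemble_precursor <- function(probe, params = design_params()) {
  stopifnot(inherits(probe, "mip_probe"), probe$status == "designed")
  motif <- params$earI_motif
  combos <- expand.grid(
    cut5 = c(params$cut_spacer_5, params$spacer_alternatives$cut_spacer_5),
    cut3 = c(params$cut_spacer_3, params$spacer_alternatives$cut_spacer_3),
    sp5 = c(params$spacer_5, params$spacer_alternatives$spacer_5),
    sp3 = c(params$spacer_3, params$spacer_alternatives$spacer_3),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(combos))) {
    co <- combos[ci, ]
    for (try in 1:25) {
      barcode <- paste(sample(c("A", "C", "G", "T"),
                              params$barcode_length, replace = TRUE),
                       collapse = "")
      mip <- paste0(probe$lig$seq, params$backbone_seq, barcode,
                    probe$ext$seq)
      precursor <- paste0(params$amp_f, co$sp5, motif, co$cut5,
                          mip,
                          co$cut3, revcomp(motif), co$sp3, params$amp_r)
      hits <- find_motif_both_strands(precursor, motif)
      if (sum(hits$strand == "+") != 1L || sum(hits$strand == "-") != 1L)
        next
      frags <- digest_earI(precursor, motif)
      if (length(frags) == 3L && frags[2L] == mip)
        return(list(barcode = barcode, mip = mip, precursor = precursor))
    }
  }
  stop("precursor assembly failed: could not avoid junction EarI motifs")
}
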