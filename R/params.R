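#' Panel design parameters
#'
#' Defaults encode the duplex-MIP design rules: 100-bp target tiles stepped by
#' 50 bp (2x tiling), 25 arm candidates per side (lengths 21-25 x shifts 0-4),
#' arm selection toward Tm 60 C and GC 50%, exclusion of EarI sites, genomic
#' redundancy, homopolymers longer than 8 and GC outside (10, 90), gap-fill
#' lengths 100-116, and a 10-nt random barcode. The EarI cassettes, spacers,
#' backbone and amplification primer regions parameterise precursor assembly;
#' all fixed sequences are validated to be free of the EarI motif on both
#' strands.
#'
#' @param tile_length Target tile length, bases.
#' @param tile_overlap Overlap of consecutive tiles, bases (< `tile_length`).
#' @param arm_lengths Candidate arm lengths, bases.
#' @param shifts Candidate outward shifts of the annealing region, bases.
#' @param tm_opt,gc_opt Optima for arm selection (degrees C, percent).
#' @param gc_min,gc_max Exclusion bounds on arm GC, percent (exclusive).
#' @param max_homopolymer Longest tolerated homopolymer run, bases.
#' @param gapfill_min,gapfill_max Allowed gap-fill lengths, bases.
#' @param barcode_length Unique-barcode length, nucleotides.
#' @param earI_motif Type IIS recognition site forbidden in arms.
#' @param amp_f,amp_r Amplification-primer regions flanking the precursor.
#' @param backbone_seq Constant probe-backbone region (post-capture primer
#'   landing) between the ligation arm and the barcode.
#' @param spacer_5,spacer_3 Outer spacers between primer regions and EarI
#'   cassettes.
#' @param cut_spacer_5 1-nt cut offset 3' of the left CTCTTC (top-strand cut
#'   lands at the MIP 5' terminus).
#' @param cut_spacer_3 4-nt cut offset between the MIP 3' terminus and the
#'   mirrored site (top-strand cut of the bottom-strand site is 4 nt out).
#' @param spacer_alternatives Named list of fallback sequences tried when a
#'   junction with a barcode or arm creates a spurious EarI motif.
#' @param thermo A [thermo_model()].
#' @return An object of class `design_params`.
#' @export
design_params <- function(tile_length = 100L,
                          tile_overlap = 50L,
                          arm_lengths = 21:25,
                          shifts = 0:4,
                          tm_opt = 60,
                          gc_opt = 50,
                          gc_min = 10,
                          gc_max = 90,
                          max_homopolymer = 8L,
                          gapfill_min = 100L,
                          gapfill_max = 116L,
                          barcode_length = 10L,
                          earI_motif = "CTCTTC",
                          amp_f = "ATCGCACCAGCGTGTACGAC",
                          amp_r = "GACGCTAGTGCATGACGGTT",
                          backbone_seq = "CATTGCGTGAACCGACATGA",
                          spacer_5 = "ACAC",
                          spacer_3 = "TGTG",
                          cut_spacer_5 = "T",
                          cut_spacer_3 = "TCGT",
                          spacer_alternatives = list(
                            cut_spacer_5 = c("A", "C", "G"),
                            cut_spacer_3 = c("ATCA", "GTAC", "CATG"),
                            spacer_5 = c("ATGC", "CAGT"),
                            spacer_3 = c("TCAG", "GATC")),
                          thermo = thermo_model()) {
  p <- list(tile_length = as.integer(tile_length),
            tile_overlap = as.integer(tile_overlap),
            arm_lengths = sort(as.integer(arm_lengths)),
            shifts = sort(as.integer(shifts)),
            tm_opt = tm_opt, gc_opt = gc_opt,
            gc_min = gc_min, gc_max = gc_max,
            max_homopolymer = as.integer(max_homopolymer),
            gapfill_min = as.integer(gapfill_min),
            gapfill_max = as.integer(gapfill_max),
            barcode_length = as.integer(barcode_length),
            earI_motif = earI_motif,
            amp_f = amp_f, amp_r = amp_r, backbone_seq = backbone_seq,
            spacer_5 = spacer_5, spacer_3 = spacer_3,
            cut_spacer_5 = cut_spacer_5, cut_spacer_3 = cut_spacer_3,
            spacer_alternatives = spacer_alternatives,
            thermo = thermo)
  stopifnot(p$tile_overlap < p$tile_length,
            p$barcode_length >= 1L,
            nchar(p$cut_spacer_5) == 1L,
            nchar(p$cut_spacer_3) == 4L,
            all(p$shifts >= 0L), all(p$arm_lengths >= 8L))
  d_max <- (max(p$arm_lengths) - min(p$arm_lengths)) + max(p$shifts)
  if (p$gapfill_min != p$tile_length ||
      p$gapfill_max != p$tile_length + 2L * d_max)
    stop("gap-fill bounds inconsistent with tile length and arm geometry")
  for (f in c("amp_f", "amp_r", "backbone_seq", "spacer_5", "spacer_3")) {
    if (nrow(find_motif_both_strands(p[[f]], p$earI_motif)) > 0L)
      stop(f, " contains the EarI motif")
  }
  structure(p, class = "design_params")
}

#' Capture-simulation parameters
#'
#' Study conditions for the synthetic capture generator. Defaults emulate the
#' statistical structure of deep duplex-MIP capture data: lognormally
#' dispersed per-probe abundance (sdlog 1.3 reproduces a ~60% within-10-fold
#' uniformity scale; meanlog = -sdlog^2/2 keeps the abundance factor unit
#' mean), a geometric PCR duplicate-count model with mean `dup_mean` extra
#' copies per molecule (2.45 corresponds to the ~71% average duplicate
#' fraction of deep capture runs, since the expected duplicate fraction is
#' r/(1+r)), 150-base reads, 1e-3 substitution errors and mean base quality
#' Q33.
#'
#' @param genome_length Simulated reference length, bases (>= 10 kb for
#'   [simulate_reference_with_variants()]).
#' @param n_variants Number of planted SNVs.
#' @param het_fraction Fraction of planted SNVs that are heterozygous (the
#'   rest are homozygous alternate).
#' @param abundance_sdlog,abundance_meanlog Lognormal per-probe abundance
#'   factor parameters.
#' @param mean_events Mean capture events per probe (Poisson, scaled by the
#'   abundance factor).
#' @param dup_mean Mean number of PCR duplicate copies per molecule
#'   (geometric); 0 means every molecule is unique.
#' @param error_rate Per-base substitution error rate in reads.
#' @param mean_q,q_jitter Mean Phred base quality and its per-base s.d.
#' @param read_length Read length, bases; must be at least
#'   barcode + longest arm + 1.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 50000L,
                       n_variants = 50L,
                       het_fraction = 0.5,
                       abundance_sdlog = 1.3,
                       abundance_meanlog = -abundance_sdlog^2 / 2,
                       mean_events = 100,
                       dup_mean = 2.45,
                       error_rate = 1e-3,
                       mean_q = 33,
                       q_jitter = 3,
                       read_length = 150L) {
  p <- list(genome_length = as.integer(genome_length),
            n_variants = as.integer(n_variants),
            het_fraction = het_fraction,
            abundance_sdlog = abundance_sdlog,
            abundance_meanlog = abundance_meanlog,
            mean_events = mean_events,
            dup_mean = dup_mean,
            error_rate = error_rate,
            mean_q = mean_q, q_jitter = q_jitter,
            read_length = as.integer(read_length))
  stopifnot(p$het_fraction >= 0, p$het_fraction <= 1,
            p$abundance_sdlog >= 0, p$mean_events >= 0,
            p$dup_mean >= 0, p$error_rate >= 0, p$error_rate < 1,
            p$read_length >= 36L)
  structure(p, class = "sim_params")
}

#' Read-processing and deduplication parameters
#'
#' @param max_mismatch Mismatches tolerated per arm during identification.
#' @param q_floor Base-quality floor Q for the representative score: with
#'   `score_mode = "qfloor"` the score of a read pair is the sum of base
#'   qualities that are >= Q over both mates (the Picard-style reading of
#'   "highest sum of base quality scores >= 15"); `"total"` uses the plain
#'   sum of all base qualities.
#' @param gapfill_min,gapfill_max Valid gap-fill length bounds, bases.
#' @param subsample_size Default subsample for percent-unique normalisation.
#' @param fold_windows Fold ranges for the uniformity metric.
#' @param score_mode See `q_floor`.
#' @return An object of class `dedup_params`.
#' @export
dedup_params <- function(max_mismatch = 1L,
                         q_floor = 15L,
                         gapfill_min = 100L,
                         gapfill_max = 116L,
                         subsample_size = 2e6,
                         fold_windows = c(10, 100),
                         score_mode = c("qfloor", "total")) {
  p <- list(max_mismatch = as.integer(max_mismatch),
            q_floor = as.integer(q_floor),
            gapfill_min = as.integer(gapfill_min),
            gapfill_max = as.integer(gapfill_max),
            subsample_size = subsample_size,
            fold_windows = fold_windows,
            score_mode = match.arg(score_mode))
  stopifnot(p$max_mismatch >= 0L, p$q_floor >= 0L,
            p$gapfill_min <= p$gapfill_max, all(p$fold_windows > 1))
  structure(p, class = "dedup_params")
}
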