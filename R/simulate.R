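#' Simulate a reference sequence with planted variants
#'
#' Generates a uniform-random genome and plants SNVs at distinct positions;
#' each SNV is heterozygous with probability `het_fraction`, otherwise
#' homozygous alternate. Deterministic under `seed`.
#'
#' @param params A [sim_params()] (genome length >= 10 kb).
#' @param seed Integer RNG seed; `NULL` uses the current stream.
#' @param contig Contig name for the simulated sequence.
#' @return List with `genome` (a [reference_genome()]) and `variants`
#'   (data.frame: `contig`, `pos` 0-based, `ref`, `alt`, `genotype`
#'   "het"/"hom").
#' @export
simulate_reference_with_variants <- function(params = sim_params(),
                                             seed = NULL,
                                             contig = "sim1") {
  if (!is.null(seed)) set.seed(seed)
  L <- params$genome_length
  if (L < 10000L) stop("genome length must be >= 10 kb")
  if (params$n_variants > L) stop("more variants than positions")
  bases <- c("A", "C", "G", "T")
  seq <- paste(sample(bases, L, replace = TRUE), collapse = "")
  genome <- reference_genome(stats::setNames(seq, contig))
  nv <- params$n_variants
  if (nv > 0L) {
    pos <- sort(sample.int(L, nv)) - 1L
    ref <- substring(seq, pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1), USE.NAMES = FALSE)
    genotype <- ifelse(stats::runif(nv) < params$het_fraction, "het", "hom")
    variants <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                           genotype = genotype, stringsAsFactors = FALSE)
  } else {
    variants <- data.frame(contig = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           genotype = character(0), stringsAsFactors = FALSE)
  }
  list(genome = genome, variants = variants)
}

#' Simulate capture products for a designed panel
#'
#' Per probe, the number of independent circularization events is Poisson
#' with mean `mean_events` scaled by a lognormal abundance factor; each event
#' receives a fresh i.i.d. random barcode, carries either allele of a
#' heterozygous site with probability 1/2 (homozygous-alt sites always carry
#' the alternate), and is amplified into `1 + Geometric(dup_mean)` PCR
#' copies. Copies of one event share barcode and allele, so the expected
#' duplicate fraction is `dup_mean / (1 + dup_mean)`.
#'
#' @param probes Probe table (from [design_panel()] or [load_probe_table()]).
#' @param genome The [reference_genome()] the probes were designed on.
#' @param variants Variant table as from
#'   [simulate_reference_with_variants()] (may be empty).
#' @param params A [sim_params()].
#' @param seed Integer RNG seed; `NULL` uses the current stream.
#' @return A list of class `mip_capture_sim` with `truth` (data.frame:
#'   `event_id`, `probe_id`, `barcode`, `allele`, `copies`) and `molecules`
#'   (data.frame: `event_id`, `probe_id`, `barcode`, `gapfill`, `copies`).
#' @export
simulate_capture_products <- function(probes, genome, variants = NULL,
                                      params = sim_params(), seed = NULL) {
  if (inherits(probes, "mip_panel")) probes <- probes$probes
  if (!is.null(seed)) set.seed(seed)
  if (is.null(variants))
    variants <- data.frame(contig = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           genotype = character(0))
  np <- nrow(probes)
  factor <- stats::rlnorm(np, params$abundance_meanlog,
                          params$abundance_sdlog)
  n_events <- stats::rpois(np, params$mean_events * factor)
  rows <- vector("list", np)
  for (i in seq_len(np)) {
    n <- n_events[i]
    if (n == 0L) next
    pb <- probes[i, ]
    base_gf <- .ref_substr(genome, pb$contig, pb$gapfill_start,
                           pb$gapfill_end)
    v <- variants[variants$contig == pb$contig &
                    variants$pos >= pb$gapfill_start &
                    variants$pos < pb$gapfill_end, , drop = FALSE]
    off <- v$pos - pb$gapfill_start + 1L
    hom <- which(v$genotype == "hom")
    for (j in hom) substr(base_gf, off[j], off[j]) <- v$alt[j]
    het <- which(v$genotype == "het")
    gf <- rep(base_gf, n)
    allele <- rep("ref", n)
    for (j in het) {
      takes_alt <- stats::runif(n) < 0.5
      for (k in which(takes_alt))
        substr(gf[k], off[j], off[j]) <- v$alt[j]
      allele <- ifelse(takes_alt, ifelse(allele == "ref", "alt",
                                         paste0(allele, "+alt")), allele)
    }
    barcodes <- .random_barcodes(n, 10L)
    rows[[i]] <- data.frame(probe_id = pb$probe_id, barcode = barcodes,
                            allele = allele, gapfill = gf,
                            stringsAsFactors = FALSE)
  }
  mol <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(mol))
    mol <- data.frame(probe_id = character(0), barcode = character(0),
                      allele = character(0), gapfill = character(0),
                      stringsAsFactors = FALSE)
  nm <- nrow(mol)
  copies <- if (params$dup_mean > 0)
    1L + stats::rgeom(nm, 1 / (1 + params$dup_mean)) else rep(1L, nm)
  mol$event_id <- seq_len(nm)
  mol$copies <- copies
  truth <- mol[, c("event_id", "probe_id", "barcode", "allele", "copies")]
  molecules <- mol[, c("event_id", "probe_id", "barcode", "gapfill",
                       "copies")]
  structure(list(truth = truth, molecules = molecules),
            class = "mip_capture_sim")
}

#' Emit paired-end reads for simulated capture molecules
#'
#' Amplicon top strand: AmpF region, barcode, extension arm, gap-fill,
#' ligation arm, reverse-complemented AmpR region. R1 is the first
#' `read_length` bases after the AmpF region; R2 is the reverse complement of
#' the last `read_length` bases before the AmpR region. Per-base substitution
#' errors are applied at `error_rate`; Phred qualities are drawn around
#' `mean_q`. Read ids encode the truth event id and copy number (testing
#' only).
#'
#' @param sim A `mip_capture_sim` from [simulate_capture_products()] (or its
#'   `molecules` data.frame, which must carry a `copies` column).
#' @param probes The probe table.
#' @param params A [sim_params()].
#' @param design A [design_params()] supplying the AmpF/AmpR regions.
#' @param seed Integer RNG seed; `NULL` uses the current stream.
#' @return A data.frame of class `mip_read_pairs`: `id`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual` (qualities Phred+33).
#' @export
emit_read_pairs <- function(sim, probes, params = sim_params(),
                            design = design_params(), seed = NULL) {
  mol <- if (inherits(sim, "mip_capture_sim")) sim$molecules else sim
  if (inherits(probes, "mip_panel")) probes <- probes$probes
  if (!is.null(seed)) set.seed(seed)
  i <- match(mol$probe_id, probes$probe_id)
  if (anyNA(i)) stop("molecule references unknown probe id")
  core <- paste0(mol$barcode, probes$ext_seq[i], mol$gapfill,
                 probes$lig_seq[i])
  rl <- params$read_length
  if (any(nchar(core) < rl))
    stop("read length exceeds amplicon core length")
  amplicon <- paste0(design$amp_f, core,
                     vapply(design$amp_r, revcomp, character(1),
                            USE.NAMES = FALSE))
  idx <- rep(seq_len(nrow(mol)), mol$copies)
  copy_no <- sequence(mol$copies)
  n <- length(idx)
  off <- nchar(design$amp_f)
  r1 <- substr(amplicon[idx], off + 1L, off + rl)
  e2 <- nchar(amplicon[idx]) - nchar(design$amp_r)
  r2raw <- substr(amplicon[idx], e2 - rl + 1L, e2)
  r2 <- vapply(r2raw, revcomp, character(1), USE.NAMES = FALSE)
  r1 <- .inject_errors(r1, params$error_rate)
  r2 <- .inject_errors(r2, params$error_rate)
  out <- data.frame(
    id = sprintf("sim:evt%d:cp%d", mol$event_id[idx], copy_no),
    r1_seq = r1, r1_qual = .random_quals(n, rl, params),
    r2_seq = r2, r2_qual = .random_quals(n, rl, params),
    stringsAsFactors = FALSE)
  class(out) <- c("mip_read_pairs", class(out))
  out
}

#' Write simulated read pairs as paired FASTQ (Phred+33)
#'
#' @param reads A `mip_read_pairs` data.frame.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  for (side in 1:2) {
    seqs <- Biostrings::DNAStringSet(
      reads[[if (side == 1) "r1_seq" else "r2_seq"]])
    names(seqs) <- reads$id
    quals <- Biostrings::BStringSet(
      reads[[if (side == 1) "r1_qual" else "r2_qual"]])
    # writeXStringSet warns that the qualities metadata column is dropped
    # from the returned object; the FASTQ on disk carries them
    suppressWarnings(Biostrings::writeXStringSet(
      seqs, if (side == 1) r1_path else r2_path,
      format = "fastq", qualities = quals))
  }
  invisible(c(r1_path, r2_path))
}

#' Write a reference genome as FASTA
#'
#' @param genome A [reference_genome()].
#' @param path Output path.
#' @export
write_reference_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

# ---- internal ---------------------------------------------------------------

.random_barcodes <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(nchar(reads[i]), nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old),
                                       1L)
    }
  }
  reads
}

.random_quals <- function(n, len, params) {
  if (n == 0L) return(character(0))
  q <- round(stats::rnorm(n * len, params$mean_q, params$q_jitter))
  q <- pmin(pmax(q, 2L), 40L)
  m <- matrix(q + 33L, nrow = n)
  vapply(seq_len(n), function(i) intToUtf8(m[i, ]), character(1))
}
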