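#' Reverse complement of a DNA string
#'
#' Works on plain character strings over the alphabet A/C/G/T/N. This is the
#' workhorse for Crick-strand handling throughout the package; arm metrics are
#' always computed on the Watson strand, the complement strand is implicit.
#'
#' @param seq A single DNA string (may be empty).
#' @return The reverse complement, as a character string.
#' @examples
#' revcomp("CTCTTC")  # "GAAGAG", the EarI site pair
#' @export
revcomp <- function(seq) {
  .check_dna(seq, allow_n = TRUE, allow_empty = TRUE)
  if (nchar(seq) == 0L) return("")
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", seq))))
}

#' GC content of a DNA string, in percent
#'
#' @param seq A non-empty A/C/G/T string.
#' @return Percent G+C in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  .check_dna(seq, allow_n = FALSE, allow_empty = FALSE)
  100 * (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}

#' Longest homopolymer run
#'
#' Length of the longest run of identical consecutive bases. The designer
#' excludes arm candidates whose longest run exceeds eight bases.
#'
#' @param seq A non-empty DNA string.
#' @return Integer run length (>= 1).
#' @export
max_homopolymer_run <- function(seq) {
  .check_dna(seq, allow_n = TRUE, allow_empty = FALSE)
  max(rle(strsplit(seq, "", fixed = TRUE)[[1]])$lengths)
}

#' Find a motif on both strands
#'
#' Reports every start position of `motif` and of `revcomp(motif)` within
#' `seq`, including overlapping occurrences. Positions are 0-based. A hit of
#' the reverse-complemented motif is reported on the minus strand at the
#' position of its Watson-strand footprint. For a palindromic motif the minus
#' strand hits duplicate the plus-strand hits and both are reported.
#'
#' @param seq DNA string to scan.
#' @param motif Non-empty motif (e.g. the EarI recognition site "CTCTTC").
#' @return A data.frame with columns `pos` (0-based start) and `strand`
#'   ("+"/"-"), ordered by position then strand.
#' @export
find_motif_both_strands <- function(seq, motif) {
  .check_dna(seq, allow_n = TRUE, allow_empty = TRUE)
  .check_dna(motif, allow_n = FALSE, allow_empty = FALSE)
  hit0 <- function(s, m) {
    if (nchar(s) < nchar(m)) return(integer(0))
    p <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
    if (p[1] == -1L) integer(0) else as.integer(p) - 1L
  }
  fwd <- hit0(seq, motif)
  rev <- hit0(seq, revcomp(motif))
  out <- data.frame(
    pos = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE
  )
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Nearest-neighbor thermodynamic model
#'
#' Dinucleotide stacking enthalpies (kcal/mol) and entropies (cal/mol/K) of the
#' unified nearest-neighbor parameter set, with duplex initiation terms for
#' terminal A.T and G.C pairs and a symmetry correction for self-complementary
#' oligos. All 16 dinucleotide lookups resolve through the reverse-complement
#' symmetry of the 10 unique stacks. Strand concentration `c_total` and the
#' monovalent salt concentration are exposed so the whole model can be swapped
#' or re-parameterised.
#'
#' @param c_total Total strand concentration, molar. Default 0.25e-6 (0.25 uM).
#' @param na_molar Monovalent cation concentration, molar. Default 0.05 (50 mM);
#'   the salt correction adds `0.368 * (N - 1) * log(na_molar)` cal/mol/K to
#'   the duplex entropy.
#' @return An object of class `thermo_model`.
#' @export
thermo_model <- function(c_total = 0.25e-6, na_molar = 0.05) {
  stopifnot(is.numeric(c_total), c_total > 0,
            is.numeric(na_molar), na_molar > 0)
  # 10 unique stacks; the other 6 filled in by reverse-complement symmetry
  dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  mirror <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA", CC = "GG")
  dh[names(mirror)] <- dh[mirror]
  ds[names(mirror)] <- ds[mirror]
  structure(list(
    dh = dh, ds = ds,
    init_gc = c(dh = 0.1, ds = -2.8),   # per G.C terminal pair
    init_at = c(dh = 2.3, ds = 4.1),    # per A.T terminal pair
    sym_ds = -1.4,                      # self-complementary correction
    c_total = c_total,
    na_molar = na_molar,
    R = 1.9872                          # gas constant, cal/mol/K
  ), class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("Nearest-neighbor thermodynamic model (unified parameter set)\n")
  cat(sprintf("  C_T = %.3g M, [Na+] = %.3g M, entropic salt correction\n",
              x$c_total, x$na_molar))
  invisible(x)
}

#' Duplex melting temperature by the nearest-neighbor method
#'
#' Tm = 1000 * dH / (dS_salt + R * ln(C_T / x)) - 273.15, where dH (kcal/mol)
#' and dS (cal/mol/K) are summed over nearest-neighbor stacks plus initiation
#' terms, the salt correction `0.368 (N-1) ln[Na+]` is applied to dS, and
#' x = 4 for non-self-complementary duplexes (1 for self-complementary, with
#' the symmetry entropy correction).
#'
#' @param seq A/C/G/T string, length >= 8 (shorter arms never occur).
#' @param model A [thermo_model()].
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq, model = thermo_model()) {
  .check_dna(seq, allow_n = FALSE, allow_empty = FALSE)
  n <- nchar(seq)
  if (n < 8L)
    stop("melting_temp requires length >= 8, got ", n)
  stacks <- substring(seq, 1:(n - 1L), 2:n)
  dh <- sum(model$dh[stacks])
  ds <- sum(model$ds[stacks])
  ends <- substring(seq, c(1L, n), c(1L, n))
  for (b in ends) {
    term <- if (b %in% c("G", "C")) model$init_gc else model$init_at
    dh <- dh + term[["dh"]]
    ds <- ds + term[["ds"]]
  }
  selfcomp <- identical(revcomp(seq), seq)
  if (selfcomp) ds <- ds + model$sym_ds
  ds <- ds + 0.368 * (n - 1L) * log(model$na_molar)
  k <- model$c_total / (if (selfcomp) 1 else 4)
  1000 * dh / (ds + model$R * log(k)) - 273.15
}

# ---- internal ---------------------------------------------------------------

.check_dna <- function(seq, allow_n = TRUE, allow_empty = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("expected a single character string")
  if (!allow_empty && nchar(seq) == 0L)
    stop("empty sequence not allowed")
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pat, seq)
  if (bad != -1L)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(seq, bad, bad), as.integer(bad)))
  invisible(TRUE)
}
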