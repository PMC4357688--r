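#' Identify probes and extract barcodes/gap-fills from paired capture reads
#'
#' R1 is expected to start with the 10-nt barcode followed by the extension
#' arm; R2 starts with the reverse-complemented ligation arm. Arms are matched
#' against the probe table allowing up to `max_mismatch` mismatches per arm;
#' a read pair is identified only when a single probe is the unique best
#' match (ties are flagged ambiguous and left unidentified). The gap-fill is
#' merged from both mates, resolving overlap disagreements by the
#' higher-quality base (ties keep the R1 base); its length is verified
#' against the mate overlap and pairs outside the valid gap-fill bounds
#' (100-116 by default) are flagged `length_valid = FALSE` and excluded from
#' deduplication.
#'
#' @param r1,r2 FASTQ paths (Phred+33), or pass a `mip_read_pairs` data.frame
#'   as `r1` with `r2 = NULL`.
#' @param probes Probe table from [design_panel()] or [load_probe_table()].
#' @param params A [dedup_params()].
#' @return A data.frame of capture records, one row per read pair: `read_id`,
#'   `probe_id`, `barcode`, `gapfill`, `gapfill_qual`, `gapfill_len`,
#'   `score` (sum of base qualities >= the quality floor over both mates),
#'   `arms_found`, `length_valid`, `ambiguous`.
#' @export
process_read_pairs <- function(r1, r2 = NULL, probes,
                               params = dedup_params()) {
  if (inherits(probes, "mip_panel")) probes <- probes$probes
  rd <- .as_read_tables(r1, r2)
  n <- nrow(rd)
  bl <- 10L
  qlist1 <- lapply(rd$r1_qual, function(q) utf8ToInt(q) - 33L)
  qlist2 <- lapply(rd$r2_qual, function(q) utf8ToInt(q) - 33L)
  score <- vapply(seq_len(n), function(i) {
    q <- c(qlist1[[i]], qlist2[[i]])
    if (params$score_mode == "qfloor") sum(q[q >= params$q_floor])
    else sum(q)
  }, numeric(1))

  lig_rc <- vapply(probes$lig_seq, revcomp, character(1), USE.NAMES = FALSE)
  ext_lens <- sort(unique(probes$ext_l))
  lig_lens <- sort(unique(probes$lig_l))
  # fast path: exact extension-arm hit, then exact ligation confirmation
  probe_idx <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  need_scan <- rep(TRUE, n)
  if (nrow(probes) > 0L && n > 0L) {
    hit_count <- integer(n)
    hit_probe <- rep(NA_integer_, n)
    for (l in ext_lens) {
      sel <- which(probes$ext_l == l)
      key <- substr(rd$r1_seq, bl + 1L, bl + l)
      m <- match(key, probes$ext_seq[sel])
      got <- !is.na(m)
      hit_count[got] <- hit_count[got] + 1L
      hit_probe[got] <- sel[m[got]]
    }
    dup_ext <- unique(probes$ext_seq[duplicated(probes$ext_seq)])
    one <- which(hit_count == 1L)
    if (length(one)) {
      p <- hit_probe[one]
      uniq_arm <- !(probes$ext_seq[p] %in% dup_ext)
      exact_lig <- substr(rd$r2_seq[one], 1L, probes$lig_l[p]) == lig_rc[p]
      res <- one[exact_lig & uniq_arm]
      probe_idx[res] <- hit_probe[res]
      need_scan[res] <- FALSE
    }
  }
  # fallback: full mismatch scan for unresolved reads
  for (i in which(need_scan)) {
    ext_sub <- vapply(ext_lens, function(l)
      substr(rd$r1_seq[i], bl + 1L, bl + l), character(1))
    names(ext_sub) <- ext_lens
    lig_sub <- vapply(lig_lens, function(l)
      substr(rd$r2_seq[i], 1L, l), character(1))
    names(lig_sub) <- lig_lens
    mm_ext <- vapply(seq_len(nrow(probes)), function(p)
      .hamming(ext_sub[[as.character(probes$ext_l[p])]], probes$ext_seq[p]),
      integer(1))
    mm_lig <- vapply(seq_len(nrow(probes)), function(p)
      .hamming(lig_sub[[as.character(probes$lig_l[p])]], lig_rc[p]),
      integer(1))
    ok <- mm_ext <= params$max_mismatch & mm_lig <= params$max_mismatch
    if (!any(ok)) next
    tot <- mm_ext + mm_lig
    best <- min(tot[ok])
    cand <- which(ok & tot == best)
    if (length(cand) > 1L) ambiguous[i] <- TRUE else probe_idx[i] <- cand
  }

  arms_found <- !is.na(probe_idx)
  barcode <- ifelse(arms_found, substr(rd$r1_seq, 1L, bl), NA_character_)
  gapfill <- rep(NA_character_, n)
  gapfill_qual <- rep(NA_character_, n)
  gapfill_len <- rep(NA_integer_, n)
  length_valid <- rep(FALSE, n)
  for (i in which(arms_found)) {
    p <- probes[probe_idx[i], ]
    mg <- .merge_gapfill(rd$r1_seq[i], qlist1[[i]], rd$r2_seq[i],
                         qlist2[[i]], p$ext_l, p$lig_l, p$gapfill_len,
                         params)
    gapfill[i] <- mg$seq
    gapfill_qual[i] <- mg$qual
    gapfill_len[i] <- mg$len
    length_valid[i] <- mg$len >= params$gapfill_min &&
      mg$len <= params$gapfill_max
  }
  data.frame(read_id = rd$id,
             probe_id = ifelse(arms_found, probes$probe_id[probe_idx],
                               NA_character_),
             barcode = barcode, gapfill = gapfill,
             gapfill_qual = gapfill_qual, gapfill_len = gapfill_len,
             score = score, arms_found = arms_found,
             length_valid = length_valid, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Remove PCR duplicates by (probe, barcode) key
#'
#' Read pairs sharing the same probe (arm-sequence combination) and unique
#' barcode are PCR duplicates of one circularized capture product. Per key,
#' the record with the highest representative score is kept (ties broken by
#' lexicographically smallest read id); output is ordered by probe id then
#' barcode, so deduplication is deterministic and idempotent.
#'
#' @param records Capture records from [process_read_pairs()]; rows that are
#'   not arm-identified or length-valid are ignored.
#' @return List with `unique` (kept records) and `n_duplicates`.
#' @export
deduplicate <- function(records) {
  valid <- records
  if (!is.null(records$arms_found))
    valid <- records[records$arms_found & records$length_valid, ,
                     drop = FALSE]
  if (nrow(valid) == 0L)
    return(list(unique = valid, n_duplicates = 0L))
  key <- paste0(valid$probe_id, "\t", valid$barcode)
  ord <- order(key, -valid$score, valid$read_id, method = "radix")
  keep <- valid[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  keep <- keep[order(keep$probe_id, keep$barcode, method = "radix"), ,
               drop = FALSE]
  rownames(keep) <- NULL
  list(unique = keep, n_duplicates = nrow(valid) - nrow(keep))
}

#' Capture accounting statistics
#'
#' Read accounting (total, arm-identified, gap-length-valid, unique), the
#' duplicate fraction `1 - unique/valid`, and per-probe unique-read counts —
#' the quantification of circularized capture products.
#'
#' @param records Capture records from [process_read_pairs()].
#' @param probes Probe table (supplies the probe universe; probes with zero
#'   unique reads are reported as undetected).
#' @return An object of class `mip_capture_stats`.
#' @export
capture_stats <- function(records, probes) {
  if (inherits(probes, "mip_panel")) probes <- probes$probes
  ded <- deduplicate(records)
  valid <- sum(records$arms_found & records$length_valid)
  counts <- table(factor(ded$unique$probe_id, levels = probes$probe_id))
  per_probe <- stats::setNames(as.integer(counts), names(counts))
  structure(list(
    total = nrow(records),
    identified = sum(records$arms_found),
    valid = valid,
    unique = nrow(ded$unique),
    n_duplicates = ded$n_duplicates,
    duplicate_fraction = if (valid > 0) 1 - nrow(ded$unique) / valid else 0,
    per_probe_unique = per_probe,
    probes_detected = sum(per_probe >= 1L)
  ), class = "mip_capture_stats")
}

#' @export
print.mip_capture_stats <- function(x, ...) {
  cat("Capture statistics\n")
  cat(sprintf("  read pairs:      %d\n", x$total))
  cat(sprintf("  arm-identified:  %d\n", x$identified))
  cat(sprintf("  gap-length valid:%d\n", x$valid))
  cat(sprintf("  unique:          %d (duplicate fraction %.1f%%)\n",
              x$unique, 100 * x$duplicate_fraction))
  cat(sprintf("  probes detected: %d of %d\n", x$probes_detected,
              length(x$per_probe_unique)))
  invisible(x)
}

#' Percent unique reads at a fixed sequencing depth
#'
#' Unique-read percentage depends on depth (deeper sequencing re-samples the
#' same capture products), so conditions are compared after subsampling to a
#' common number of reads: a seeded uniform subsample without replacement is
#' drawn and the percentage of distinct (probe, barcode) keys among it is
#' returned. In expectation this is monotone non-increasing in depth.
#'
#' @param records Capture records (only arm-identified, length-valid rows are
#'   used).
#' @param n Subsample size (e.g. 2e6); if it exceeds the record count all
#'   records are used and attribute `subsampled = FALSE` is set.
#' @param fraction Alternative to `n`: fraction of available records.
#' @param seed Integer RNG seed for the subsample.
#' @return Percent unique, in (0, 100].
#' @export
percent_unique_at_depth <- function(records, n = NULL, fraction = NULL,
                                    seed = 1L) {
  valid <- records
  if (!is.null(records$arms_found))
    valid <- records[records$arms_found & records$length_valid, ,
                     drop = FALSE]
  avail <- nrow(valid)
  if (is.null(n)) {
    if (is.null(fraction)) stop("give n or fraction")
    n <- round(fraction * avail)
  }
  if (n <= 0) stop("subsample size must be positive")
  set.seed(seed)
  full <- n >= avail
  take <- if (full) seq_len(avail) else sample.int(avail, n)
  key <- paste0(valid$probe_id[take], "\t", valid$barcode[take])
  out <- 100 * length(unique(key)) / length(take)
  attr(out, "subsampled") <- !full
  out
}

#' Capture uniformity within a fold range
#'
#' Fraction of detected probes (unique-read count >= 1) whose abundance lies
#' within a `fold`-range. The default convention slides a log10 window of
#' width log10(fold) and reports the maximally covered fraction; the
#' alternative centers the window on the median count.
#'
#' @param counts Per-probe unique-read counts (>= 0; at least one positive).
#' @param fold Fold range, e.g. 10 or 100.
#' @param method `"window"` (maximizing sliding window) or
#'   `"median_centered"`.
#' @return Fraction in (0, 1].
#' @export
uniformity <- function(counts, fold = 10,
                       method = c("window", "median_centered")) {
  method <- match.arg(method)
  counts <- counts[counts >= 1]
  if (length(counts) == 0L) stop("all counts are zero")
  lg <- sort(log10(counts))
  w <- log10(fold)
  if (method == "window") {
    hi <- findInterval(lg + w + 1e-9, lg)
    max((hi - seq_along(lg) + 1) / length(lg))
  } else {
    med <- stats::median(lg)
    mean(lg >= med - w / 2 & lg <= med + w / 2)
  }
}

#' Flag probes with variants on annealing arms
#'
#' A variant falling inside either arm's genomic span can disturb annealing
#' and depress capture; such probes are flagged. Also returns the per-probe
#' covariate table (arm Tm, GC, lengths, flag) for external regression
#' against capture yield.
#'
#' @param probes Probe table.
#' @param variants Data.frame with `contig` and `pos` (0-based) columns.
#' @return List with `flags` (named logical), `n_flagged`, and `covariates`
#'   (data.frame).
#' @export
flag_arm_variants <- function(probes, variants) {
  if (inherits(probes, "mip_panel")) probes <- probes$probes
  known <- variants$contig %in% probes$contig
  if (any(!known)) {
    warning(sum(!known), " variant(s) on unknown contig skipped")
    variants <- variants[known, , drop = FALSE]
  }
  flags <- stats::setNames(logical(nrow(probes)), probes$probe_id)
  if (nrow(variants) > 0L && nrow(probes) > 0L) {
    vgr <- GenomicRanges::GRanges(
      variants$contig, IRanges::IRanges(variants$pos + 1L, width = 1L))
    arm <- GenomicRanges::GRanges(
      rep(probes$contig, 2L),
      IRanges::IRanges(c(probes$ext_start, probes$lig_start) + 1L,
                       c(probes$ext_end, probes$lig_end)))
    hits <- GenomicRanges::countOverlaps(arm, vgr)
    flags <- flags | (hits[seq_len(nrow(probes))] +
                        hits[nrow(probes) + seq_len(nrow(probes))]) > 0L
  }
  covariates <- data.frame(
    probe_id = probes$probe_id,
    ext_tm = probes$ext_tm, ext_gc = probes$ext_gc, ext_l = probes$ext_l,
    lig_tm = probes$lig_tm, lig_gc = probes$lig_gc, lig_l = probes$lig_l,
    arm_variant = as.logical(flags),
    stringsAsFactors = FALSE)
  list(flags = flags, n_flagged = sum(flags), covariates = covariates)
}

#' Write deduplicated gap-fill reads as FASTQ for external alignment
#'
#' @param unique_records The `unique` component of [deduplicate()].
#' @param path Output FASTQ path.
#' @export
write_unique_fastq <- function(unique_records, path) {
  seqs <- Biostrings::DNAStringSet(unique_records$gapfill)
  names(seqs) <- unique_records$read_id
  suppressWarnings(Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(unique_records$gapfill_qual)))
  invisible(path)
}

# ---- internal ---------------------------------------------------------------

.as_read_tables <- function(r1, r2) {
  if (is.data.frame(r1)) return(r1)
  # the reader warns about dropped metadata columns when re-wrapping the
  # quality-scaled set; sequence and quality content are unaffected
  rd1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
  rd2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
  if (length(rd1) != length(rd2)) stop("R1/R2 read counts differ")
  data.frame(id = sub("\\s.*$", "", names(rd1)),
             r1_seq = as.character(rd1),
             r1_qual = as.character(Biostrings::quality(rd1)),
             r2_seq = as.character(rd2),
             r2_qual = as.character(Biostrings::quality(rd2)),
             stringsAsFactors = FALSE)
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(nchar(b))  # truncated read: worst case
  sum(charToRaw(a) != charToRaw(b))
}

# Merge the two mates' views of the gap-fill. R1 contributes a prefix (after
# barcode + extension arm), R2 a suffix (before the ligation arm). The
# assumed total length is the probe's designed gap-fill length, verified
# against the mate overlap; on disagreement nearby lengths are searched.
.merge_gapfill <- function(s1, q1, s2, q2, l_ext, l_lig, l_designed,
                           params) {
  bl <- 10L
  p1 <- substr(s1, bl + l_ext + 1L, nchar(s1))
  qp <- q1[(bl + l_ext + 1L):nchar(s1)]
  rc2 <- revcomp(s2)
  s2len <- nchar(rc2) - l_lig
  s2gap <- substr(rc2, 1L, s2len)
  qs <- rev(q2)[seq_len(s2len)]
  p1len <- nchar(p1)

  ov_mm <- function(L) {
    a <- max(1L, L - s2len + 1L)
    b <- min(p1len, L)
    if (b < a) return(c(NA_integer_, 0L))
    x <- substr(p1, a, b)
    y <- substr(s2gap, a - (L - s2len), b - (L - s2len))
    c(if (x == y) 0L else .hamming(x, y), b - a + 1L)
  }
  L <- l_designed
  chk <- ov_mm(L)
  tol <- function(ov) max(2, ceiling(0.1 * ov))
  if (!is.na(chk[1]) && chk[1] > tol(chk[2])) {
    cand <- setdiff(seq.int(max(20L, params$gapfill_min - 10L),
                            params$gapfill_max + 10L), L)
    best <- c(L, chk[1], chk[2])
    for (Lc in cand) {
      m <- ov_mm(Lc)
      if (is.na(m[1]) || m[2] < 15L) next
      if (m[1] / m[2] < best[2] / max(best[3], 1L)) best <- c(Lc, m[1], m[2])
    }
    L <- best[1]
  }
  # assemble: R2 suffix first, R1 prefix on top, strictly better-quality
  # R2 bases win in the overlap (ties keep R1)
  res <- character(L)
  resq <- integer(L)
  i2 <- seq.int(max(1L, L - s2len + 1L), L)
  sv <- strsplit(s2gap, "", fixed = TRUE)[[1]]
  res[i2] <- sv[i2 - (L - s2len)]
  resq[i2] <- qs[i2 - (L - s2len)]
  i1 <- seq_len(min(p1len, L))
  pv <- strsplit(p1, "", fixed = TRUE)[[1]]
  ov <- i1[i1 >= max(1L, L - s2len + 1L)]
  keep2 <- ov[resq[ov] > qp[ov]]
  put1 <- setdiff(i1, keep2)
  res[put1] <- pv[put1]
  resq[put1] <- qp[put1]
  list(seq = paste(res, collapse = ""),
       qual = intToUtf8(resq + 33L),
       len = as.integer(L))
}
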