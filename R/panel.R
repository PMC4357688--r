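#' Design a duplex-MIP panel over target regions
#'
#' Tiles the regions, designs one probe per tile (enumerate, filter, select on
#' both sides), assembles barcoded precursor oligos, and accounts for failures
#' in exactly four categories: earI, redundancy, homopolymer, gc. Fully
#' deterministic for fixed inputs and seed.
#'
#' @param regions Target regions: data.frame (`contig`, `start`, `end`,
#'   optional `name`; 0-based half-open), `GRanges`, or a BED path.
#' @param genome A [reference_genome()] (or FASTA path).
#' @param params A [design_params()].
#' @param seed Integer RNG seed (barcodes).
#' @return An object of class `mip_panel`: list with `probes` (data.frame,
#'   one row per designed probe), `failures` (data.frame with `category`),
#'   `report` (class `design_report`) and `params`.
#' @export
design_panel <- function(regions, genome, params = design_params(),
                         seed = 1L) {
  if (is.character(genome)) genome <- load_reference(genome)
  if (is.character(regions)) regions <- read_targets_bed(regions)
  set.seed(seed)
  index <- build_index(genome)
  tiles <- tile_targets(regions, params, genome)
  failed_regions <- attr(tiles, "failed")

  probe_rows <- vector("list", nrow(tiles))
  fail_rows <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    tile <- tiles[i, ]
    pr <- design_probe(tile, genome, index, params)
    if (pr$status == "designed") {
      asm <- assemble_precursor(pr, params)
      probe_rows[[i]] <- data.frame(
        probe_id = sprintf("MIP%05d", i),
        contig = tile$contig, tile_start = tile$start, tile_end = tile$end,
        region = tile$region, tile_index = tile$tile_index,
        ext_seq = pr$ext$seq, ext_l = pr$ext$l, ext_s = pr$ext$s,
        ext_d = pr$ext$d, ext_start = pr$ext$start, ext_end = pr$ext$end,
        ext_tm = pr$ext$tm, ext_gc = pr$ext$gc,
        lig_seq = pr$lig$seq, lig_l = pr$lig$l, lig_s = pr$lig$s,
        lig_d = pr$lig$d, lig_start = pr$lig$start, lig_end = pr$lig$end,
        lig_tm = pr$lig$tm, lig_gc = pr$lig$gc,
        gapfill_start = pr$gapfill_start, gapfill_end = pr$gapfill_end,
        gapfill_len = pr$gapfill_len,
        barcode = asm$barcode, mip_seq = asm$mip, precursor = asm$precursor,
        stringsAsFactors = FALSE)
    } else {
      fail_rows[[i]] <- data.frame(
        contig = tile$contig, tile_start = tile$start, tile_end = tile$end,
        region = tile$region, tile_index = tile$tile_index,
        category = pr$category, stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, probe_rows[!vapply(probe_rows, is.null,
                                              logical(1))])
  failures <- do.call(rbind, fail_rows[!vapply(fail_rows, is.null,
                                               logical(1))])
  if (is.null(probes)) probes <- .empty_probe_table()
  rownames(probes) <- NULL
  if (is.null(failures))
    failures <- data.frame(contig = character(0), tile_start = integer(0),
                           tile_end = integer(0), region = character(0),
                           tile_index = integer(0), category = character(0),
                           stringsAsFactors = FALSE)
  cat_order <- c("earI", "redundancy", "homopolymer", "gc")
  fail_counts <- vapply(cat_order,
                        function(k) sum(failures$category == k), integer(1))
  report <- structure(list(
    attempted = nrow(tiles),
    designed = nrow(probes),
    failures = fail_counts,
    failed_regions = failed_regions,
    coverage = .target_coverage(regions, probes)
  ), class = "design_report")
  structure(list(probes = probes, failures = failures, report = report,
                 params = params),
            class = "mip_panel")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Design report: %d/%d tiles designed (%.1f%%)\n",
              x$designed, x$attempted,
              if (x$attempted) 100 * x$designed / x$attempted else 0))
  for (k in names(x$failures))
    if (x$failures[[k]] > 0)
      cat(sprintf("  failed (%s): %d\n", k, x$failures[[k]]))
  if (length(x$failed_regions))
    cat("  untileable regions:", length(x$failed_regions), "\n")
  cat(sprintf("  target-base coverage by designed gap-fills: %.1f%%\n",
              100 * x$coverage))
  invisible(x)
}

#' @export
print.mip_panel <- function(x, ...) {
  cat(sprintf("Duplex-MIP panel: %d probes\n", nrow(x$probes)))
  print(x$report)
  invisible(x)
}

#' Export a designed panel to disk
#'
#' Writes the probe table (TSV), precursor oligos (FASTA), gap-fill spans
#' (BED) and the design report (JSON) into `out_dir`. The probe table
#' round-trips losslessly through [load_probe_table()].
#'
#' @param panel A `mip_panel` from [design_panel()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
export_design <- function(panel, out_dir) {
  stopifnot(inherits(panel, "mip_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(probes = file.path(out_dir, "probes.tsv"),
             precursors = file.path(out_dir, "precursors.fasta"),
             gapfills = file.path(out_dir, "gapfills.bed"),
             report = file.path(out_dir, "report.json"))
  utils::write.table(panel$probes, paths[["probes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fa <- Biostrings::DNAStringSet(stats::setNames(
    panel$probes$precursor, panel$probes$probe_id))
  Biostrings::writeXStringSet(fa, paths[["precursors"]])
  gr <- GenomicRanges::GRanges(
    panel$probes$contig,
    IRanges::IRanges(start = panel$probes$gapfill_start + 1L,
                     end = panel$probes$gapfill_end),
    name = panel$probes$probe_id)
  rtracklayer::export.bed(gr, paths[["gapfills"]])
  rep <- panel$report
  jsonlite::write_json(list(attempted = rep$attempted,
                            designed = rep$designed,
                            failures = as.list(rep$failures),
                            failed_regions = rep$failed_regions,
                            coverage = rep$coverage),
                       paths[["report"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a probe table written by [export_design()]
#'
#' @param path Path to a `probes.tsv`.
#' @return The probe data.frame.
#' @export
load_probe_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) return(.empty_probe_table())
  int_cols <- c("tile_start", "tile_end", "tile_index", "ext_l", "ext_s",
                "ext_d", "ext_start", "ext_end", "lig_l", "lig_s", "lig_d",
                "lig_start", "lig_end", "gapfill_start", "gapfill_end",
                "gapfill_len")
  num_cols <- c("ext_tm", "ext_gc", "lig_tm", "lig_gc")
  for (cl in int_cols) tab[[cl]] <- as.integer(tab[[cl]])
  for (cl in num_cols) tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}

.empty_probe_table <- function() {
  data.frame(probe_id = character(0), contig = character(0),
             tile_start = integer(0), tile_end = integer(0),
             region = character(0), tile_index = integer(0),
             ext_seq = character(0), ext_l = integer(0), ext_s = integer(0),
             ext_d = integer(0), ext_start = integer(0), ext_end = integer(0),
             ext_tm = numeric(0), ext_gc = numeric(0),
             lig_seq = character(0), lig_l = integer(0), lig_s = integer(0),
             lig_d = integer(0), lig_start = integer(0), lig_end = integer(0),
             lig_tm = numeric(0), lig_gc = numeric(0),
             gapfill_start = integer(0), gapfill_end = integer(0),
             gapfill_len = integer(0), barcode = character(0),
             mip_seq = character(0), precursor = character(0),
             stringsAsFactors = FALSE)
}

# Fraction of original target-region bases covered by >= 1 designed gap-fill.
.target_coverage <- function(regions, probes) {
  if (inherits(regions, "GRanges")) {
    regions <- data.frame(
      contig = as.character(GenomicRanges::seqnames(regions)),
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions), stringsAsFactors = FALSE)
  }
  regions <- regions[regions$end > regions$start, , drop = FALSE]
  if (nrow(regions) == 0L) return(NA_real_)
  tgt <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end)))
  total <- sum(GenomicRanges::width(tgt))
  if (nrow(probes) == 0L) return(0)
  gf <- GenomicRanges::reduce(GenomicRanges::GRanges(
    probes$contig,
    IRanges::IRanges(probes$gapfill_start + 1L, probes$gapfill_end)))
  covered <- sum(GenomicRanges::width(
    GenomicRanges::intersect(tgt, gf, ignore.strand = TRUE)))
  covered / total
}
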