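test_that("tile_targets steps by 50 and anchors the last tile to the end", {
  p <- design_params()
  t1 <- tile_targets(data.frame(contig = "c", start = 0L, end = 100L), p)
  expect_equal(nrow(t1), 1L)
  expect_equal(c(t1$start, t1$end), c(0L, 100L))

  t2 <- tile_targets(data.frame(contig = "c", start = 0L, end = 1000L), p)
  expect_equal(t2$start, seq(0L, 900L, by = 50L))
  expect_true(all(t2$end - t2$start == 100L))

  t3 <- tile_targets(data.frame(contig = "c", start = 0L, end = 130L), p)
  expect_equal(t3$start, c(0L, 30L))
  expect_equal(t3$end, c(100L, 130L))
})

test_that("short regions get one centered tile; 2x tiling covers interior bases twice", {
  p <- design_params()
  t <- tile_targets(data.frame(contig = "c", start = 500L, end = 540L), p)
  expect_equal(nrow(t), 1L)
  expect_equal(t$end - t$start, 100L)
  expect_true(t$start <= 500L && t$end >= 540L)
  expect_equal((t$start + t$end) %/% 2L, 520L)

  t2 <- tile_targets(data.frame(contig = "c", start = 0L, end = 1000L), p)
  cov <- integer(1000)
  for (i in seq_len(nrow(t2))) {
    idx <- (t2$start[i] + 1L):t2$end[i]
    cov[idx] <- cov[idx] + 1L
  }
  expect_true(all(cov[51:950] == 2L))
  expect_true(all(cov >= 1L))
})

test_that("regions leaving the contig are failed, not fatal", {
  p <- design_params()
  g <- reference_genome(c(tiny = rand_dna(500)))
  t <- tile_targets(data.frame(contig = "tiny",
                               start = c(10L, 200L), end = c(110L, 300L),
                               name = c("edge", "ok")), p, g)
  expect_equal(attr(t, "failed"), "edge")
  expect_true(all(t$region == "ok"))
})

test_that("arm enumeration yields 25 candidates with d = (25 - l) + s", {
  g <- fixture_genome()
  p <- design_params()
  tile <- data.frame(contig = "c1", start = 1000L, end = 1100L,
                     region = "r", tile_index = 1L)
  for (side in c("ext", "lig")) {
    cands <- enumerate_arm_candidates(tile, side, g, p)
    expect_equal(nrow(cands), 25L)
    expect_equal(cands$d, (25L - cands$l) + cands$s)
    expect_true(all(cands$d >= 0L & cands$d <= 8L))
    expect_true(all(cands$end - cands$start == cands$l))
  }
  ext <- enumerate_arm_candidates(tile, "ext", g, p)
  flush <- ext[ext$l == 25L & ext$s == 0L, ]
  expect_equal(flush$d, 0L)
  expect_equal(flush$seq, substr(g$seq[["c1"]], 1000L - 25L + 1L, 1000L))
  deep <- ext[ext$l == 21L & ext$s == 4L, ]
  expect_equal(deep$d, 8L)
  lig <- enumerate_arm_candidates(tile, "lig", g, p)
  expect_equal(lig$start[lig$l == 25L & lig$s == 0L], 1100L)
})

test_that("filter excludes each category and attributes the first failure", {
  set.seed(10)
  dup21 <- rand_dna(21)
  g <- reference_genome(c(c1 = paste0(rand_dna(1000), dup21, rand_dna(200),
                                      dup21, rand_dna(1000))))
  ix <- build_index(g, anchor_k = 12)
  seqs <- c(earI = paste0("ACGTACG", "CTCTTC", "ATGCATGC"),
            dup = dup21,
            homo9 = paste0("AAAAAAAAA", "CGTATGCATGCA"),
            gc_low = "ATATATATATGATATATATAT",
            homo8 = "AACCCCCCCCGTATGCATGCA",
            both = paste0("CTCTTC", "AAAAAAAAA", "CGATGC"))
  cands <- data.frame(side = "ext", l = 21L, s = 0L, d = 4L,
                      start = 0L, end = 21L, seq = unname(seqs),
                      tm = 60, gc = vapply(seqs, gc_percent, numeric(1),
                                           USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  fl <- filter_candidates(cands, ix, design_params())
  ff <- fl$flagged$first_fail
  expect_equal(ff[1], "earI")
  expect_equal(ff[2], "redundancy")
  expect_equal(ff[3], "homopolymer")
  expect_equal(ff[4], "gc")
  expect_true(is.na(ff[5]))  # 8-base run survives
  expect_equal(ff[6], "earI")  # earI wins over homopolymer in attribution
  expect_equal(fl$survivors$seq, unname(seqs["homo8"]))
  expect_equal(unname(fl$counts),
               c(2L, 1L, 1L, 1L))
})

test_that("arm selection is lexicographic in |Tm-60|, |GC-50|, length, shift", {
  p <- design_params()
  sv <- data.frame(l = c(21L, 22L), s = c(0L, 1L), tm = c(59.2, 60.7),
                   gc = c(52, 48), seq = c("a", "b"))
  expect_equal(select_best_candidate(sv, p)$seq, "b")  # |0.7| < |0.8|
  sv2 <- data.frame(l = c(21L, 21L), s = c(0L, 0L), tm = c(61, 61),
                    gc = c(48, 54), seq = c("a", "b"))
  expect_equal(select_best_candidate(sv2, p)$seq, "a")
  sv3 <- data.frame(l = 23L, s = 2L, tm = 55, gc = 30, seq = "only")
  expect_equal(select_best_candidate(sv3, p)$seq, "only")
  sv4 <- data.frame(l = c(21L, 25L), s = c(0L, 0L), tm = c(60, 60),
                    gc = c(50, 50), seq = c("short", "long"))
  expect_equal(select_best_candidate(sv4, p)$seq, "long")
  expect_error(select_best_candidate(sv4[0, ], p), "no surviving")
})

test_that("a tile whose extension flank is saturated with EarI sites fails as earI", {
  set.seed(11)
  s <- rand_dna(1000)
  # 0-based [60, 100): every possible extension-arm window contains CTCTTC
  substr(s, 61, 100) <- substr(strrep("CTCTTC", 7), 1, 40)
  g <- reference_genome(c(c1 = s))
  ix <- build_index(g)
  tile <- data.frame(contig = "c1", start = 100L, end = 200L,
                     region = "r", tile_index = 1L)
  pr <- design_probe(tile, g, ix, design_params())
  expect_equal(pr$status, "failed")
  expect_equal(pr$category, "earI")
})

test_that("designed panels respect every arm filter and the gap-fill bounds", {
  panel <- fixture_panel()
  g <- fixture_genome()
  ix <- build_index(g)
  pr <- panel$probes
  expect_equal(nrow(pr), 19L)
  expect_true(all(pr$gapfill_len >= 100L & pr$gapfill_len <= 116L))
  expect_equal(pr$gapfill_len,
               (pr$tile_end - pr$tile_start) + pr$ext_d + pr$lig_d)
  for (arm in c(pr$ext_seq, pr$lig_seq)) {
    expect_equal(nrow(find_motif_both_strands(arm, "CTCTTC")), 0L)
    expect_equal(count_occurrences(ix, arm), 1L)
    expect_lte(max_homopolymer_run(arm), 8L)
    expect_true(gc_percent(arm) > 10 && gc_percent(arm) < 90)
  }
  # arm sequences match their genomic spans (Watson strand)
  for (i in c(1L, 10L, 19L)) {
    expect_equal(pr$ext_seq[i],
                 substr(g$seq[["c1"]], pr$ext_start[i] + 1L, pr$ext_end[i]))
    expect_equal(pr$lig_seq[i],
                 substr(g$seq[["c1"]], pr$lig_start[i] + 1L, pr$lig_end[i]))
  }
})

test_that("the chosen arm attains the minimal |Tm - 60| among survivors", {
  panel <- fixture_panel()
  g <- fixture_genome()
  ix <- build_index(g)
  p <- panel$params
  for (i in 1:3) {
    pr <- panel$probes[i, ]
    tile <- data.frame(contig = pr$contig, start = pr$tile_start,
                       end = pr$tile_end, region = pr$region,
                       tile_index = pr$tile_index)
    sv <- filter_candidates(
      enumerate_arm_candidates(tile, "ext", g, p), ix, p)$survivors
    expect_equal(abs(pr$ext_tm - 60), min(abs(sv$tm - 60)))
    expect_true(pr$ext_seq %in% sv$seq)
  }
})

test_that("panel accounting conserves tiles and reports full coverage", {
  panel <- fixture_panel()
  rep <- panel$report
  expect_equal(rep$attempted, rep$designed + sum(rep$failures))
  expect_equal(rep$coverage, 1.0)
  expect_gte(rep$coverage, 0)
  expect_lte(rep$coverage, 1)
})

test_that("panel design is deterministic for fixed inputs and seed", {
  g <- fixture_genome()
  regions <- data.frame(contig = "c1", start = 30000L, end = 30200L)
  p1 <- design_panel(regions, g, seed = 5)
  p2 <- design_panel(regions, g, seed = 5)
  expect_identical(p1$probes, p2$probes)
  p3 <- design_panel(regions, g, seed = 6)
  expect_false(all(p3$probes$barcode == p1$probes$barcode))
  expect_identical(p3$probes$ext_seq, p1$probes$ext_seq)  # seed only moves barcodes
})

test_that("precursor digestion releases exactly the probe strand", {
  panel <- fixture_panel()
  for (i in c(1L, 7L, 19L)) {
    pr <- panel$probes[i, ]
    frags <- digest_earI(pr$precursor)
    expect_equal(length(frags), 3L)
    expect_equal(frags[2], pr$mip_seq)
    hits <- find_motif_both_strands(pr$precursor, "CTCTTC")
    expect_equal(sum(hits$strand == "+"), 1L)
    expect_equal(sum(hits$strand == "-"), 1L)
    expect_equal(nchar(pr$barcode), 10L)
    # barcode sits between the backbone and the extension arm
    expect_equal(pr$mip_seq,
                 paste0(pr$lig_seq, panel$params$backbone_seq, pr$barcode,
                        pr$ext_seq))
  }
})

test_that("design exports round-trip through the probe-table loader", {
  panel <- fixture_panel()
  for (k in c(0L, 1L, nrow(panel$probes))) {
    sub <- panel
    sub$probes <- panel$probes[seq_len(k), , drop = FALSE]
    rownames(sub$probes) <- NULL
    out <- file.path(tempfile(), paste0("design", k))
    paths <- export_design(sub, out)
    expect_true(all(file.exists(paths)))
    back <- load_probe_table(paths[["probes"]])
    expect_equal(back, sub$probes, tolerance = 1e-9)
    fa <- Biostrings::readDNAStringSet(paths[["precursors"]])
    expect_equal(length(fa), k)
    if (k > 0)
      expect_equal(as.character(fa[[1]]), sub$probes$precursor[1])
    rep <- jsonlite::read_json(paths[["report"]])
    expect_equal(rep$designed, panel$report$designed)
  }
})
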