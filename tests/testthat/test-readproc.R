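test_that("error-free reads are assigned to their true probes and barcodes", {
  px <- fixture_pipeline_clean()
  rec <- px$records
  expect_true(all(rec$arms_found))
  expect_true(all(rec$length_valid))
  eid <- as.integer(sub("sim:evt(\\d+):cp\\d+", "\\1", rec$read_id))
  i <- match(eid, px$sim$truth$event_id)
  expect_equal(rec$probe_id, px$sim$truth$probe_id[i])
  expect_equal(rec$barcode, px$sim$truth$barcode[i])
  expect_equal(rec$gapfill, px$sim$molecules$gapfill[i])
})

test_that("one arm substitution is tolerated at max_mismatch 1 but not 0", {
  px <- fixture_pipeline_clean()
  rd <- px$reads[1, , drop = FALSE]
  substr(rd$r1_seq, 15, 15) <- if (substr(rd$r1_seq, 15, 15) == "A") "C"
    else "A"  # inside the extension arm (positions 11..10+l)
  rec1 <- process_read_pairs(rd, NULL, px$panel,
                             dedup_params(max_mismatch = 1L))
  expect_true(rec1$arms_found)
  expect_equal(rec1$probe_id, px$records$probe_id[1])
  rec0 <- process_read_pairs(rd, NULL, px$panel,
                             dedup_params(max_mismatch = 0L))
  expect_false(rec0$arms_found)
})

test_that("reads matching two probes equally are flagged ambiguous", {
  px <- fixture_pipeline_clean()
  probes2 <- px$panel$probes[c(1, 1), ]
  probes2$probe_id <- c("A", "B")
  rd <- px$reads[px$records$probe_id == px$panel$probes$probe_id[1], ,
                 drop = FALSE][1, , drop = FALSE]
  rec <- process_read_pairs(rd, NULL, probes2)
  expect_false(rec$arms_found)
  expect_true(rec$ambiguous)
})

test_that("a truncated gap-fill is measured and flagged length-invalid", {
  panel <- fixture_panel()
  g <- fixture_genome()
  pb <- panel$probes[1, ]
  full_gf <- substr(g$seq[["c1"]], pb$gapfill_start + 1L, pb$gapfill_end)
  mol <- data.frame(event_id = 1L, probe_id = pb$probe_id,
                    barcode = "ACGTACGTAC",
                    gapfill = substr(full_gf, 1, 99), copies = 1L,
                    stringsAsFactors = FALSE)
  sp <- sim_params(error_rate = 0, dup_mean = 0)
  rd <- emit_read_pairs(mol, panel, sp, seed = 40)
  rec <- process_read_pairs(rd, NULL, panel)
  expect_true(rec$arms_found)
  expect_equal(rec$gapfill_len, 99L)
  expect_false(rec$length_valid)
  expect_equal(rec$gapfill, substr(full_gf, 1, 99))
})

test_that("deduplication keeps the best-scoring pair per (probe, barcode)", {
  recs <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    probe_id = c("P1", "P1", "P2", "P3", "P1"),
    barcode = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG"),
    score = c(300, 280, 100, 50, 10),
    stringsAsFactors = FALSE)
  d <- deduplicate(recs)
  expect_equal(d$n_duplicates, 1L)
  expect_setequal(d$unique$read_id, c("r1", "r3", "r4", "r5"))
  # ties break toward the smallest read id
  tie <- data.frame(read_id = c("b", "a"), probe_id = "P", barcode = "T",
                    score = c(5, 5), stringsAsFactors = FALSE)
  expect_equal(deduplicate(tie)$unique$read_id, "a")
  # three distinct keys pass through untouched
  three <- data.frame(read_id = c("x", "y", "z"),
                      probe_id = c("P1", "P2", "P3"), barcode = "AA",
                      score = 1, stringsAsFactors = FALSE)
  expect_equal(deduplicate(three)$n_duplicates, 0L)
})

test_that("deduplication matches a brute-force grouping oracle and is idempotent", {
  set.seed(50)
  n <- 10000L
  recs <- data.frame(
    read_id = sprintf("r%05d", sample(n)),
    probe_id = sample(sprintf("P%02d", 1:40), n, replace = TRUE),
    barcode = sample(replicate(800, rand_dna(10)), n, replace = TRUE),
    score = sample(500L, n, replace = TRUE),
    stringsAsFactors = FALSE)
  d <- deduplicate(recs)
  key <- paste(recs$probe_id, recs$barcode)
  expect_equal(nrow(d$unique), length(unique(key)))
  oracle_keep <- vapply(split(recs, key), function(grp) {
    best <- grp[grp$score == max(grp$score), , drop = FALSE]
    sort(best$read_id)[1]
  }, character(1))
  expect_setequal(d$unique$read_id, unname(oracle_keep))
  d2 <- deduplicate(d$unique)
  expect_equal(d2$n_duplicates, 0L)
  expect_equal(d2$unique, d$unique)
})

test_that("unique reads equal distinct truth events on error-free data", {
  px <- fixture_pipeline_clean()
  st <- capture_stats(px$records, px$panel)
  truth_keys <- unique(paste(px$sim$truth$probe_id, px$sim$truth$barcode))
  expect_equal(st$unique, length(truth_keys))
  expect_equal(sum(st$per_probe_unique),
               st$unique)
})

test_that("capture accounting conserves reads through each stage", {
  panel <- fixture_panel()
  sp <- sim_params(mean_events = 20, dup_mean = 0.5, error_rate = 0.02)
  sim <- simulate_capture_products(panel, fixture_genome(), NULL, sp,
                                   seed = 51)
  reads <- emit_read_pairs(sim, panel, sp, seed = 52)
  rec <- process_read_pairs(reads, NULL, panel)
  st <- capture_stats(rec, panel)
  expect_equal(st$total, nrow(reads))
  expect_gte(st$total, st$identified)
  expect_gte(st$identified, st$valid)
  expect_gte(st$valid, st$unique)
  expect_equal(st$valid, st$unique + st$n_duplicates)
  expect_equal(st$duplicate_fraction, 1 - st$unique / st$valid)
  expect_equal(st$probes_detected, sum(st$per_probe_unique >= 1))
})

test_that("percent unique is 100 for singletons and decreases with depth", {
  allu <- data.frame(probe_id = sprintf("P%03d", 1:500),
                     barcode = replicate(500, rand_dna(10)),
                     stringsAsFactors = FALSE)
  expect_equal(as.numeric(percent_unique_at_depth(allu, n = 1, seed = 1)),
               100)
  expect_equal(as.numeric(percent_unique_at_depth(allu, n = 250, seed = 1)),
               100)
  expect_error(percent_unique_at_depth(allu, n = 0), "positive")

  set.seed(53)
  copies <- 1L + stats::rgeom(2000, 1 / 4)  # heavily duplicated fixture
  dup <- data.frame(
    probe_id = rep("P", sum(copies)),
    barcode = rep(replicate(2000, rand_dna(10)), copies),
    stringsAsFactors = FALSE)
  pct <- function(fr) mean(vapply(1:20, function(s)
    as.numeric(percent_unique_at_depth(dup, fraction = fr, seed = s)),
    numeric(1)))
  p <- vapply(c(0.125, 0.25, 0.5, 1), pct, numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("uniformity reports the best-covered fold window", {
  expect_equal(uniformity(rep(7, 50), fold = 10), 1.0)
  expect_equal(uniformity(c(1, 1, 1, 100), fold = 10), 0.75)
  cnts <- c(1, 3, 9, 40, 200, 900, 1200)
  expect_gte(uniformity(cnts, fold = 100), uniformity(cnts, fold = 10))
  expect_error(uniformity(c(0, 0)), "zero")
  expect_lte(uniformity(cnts, fold = 10, method = "median_centered"),
             uniformity(cnts, fold = 10))
})

test_that("variants on annealing arms are flagged; gap-fill variants are not", {
  panel <- fixture_panel()
  pr <- panel$probes
  v_arm <- data.frame(contig = pr$contig[1], pos = pr$ext_start[1] + 2L)
  f1 <- flag_arm_variants(panel, v_arm)
  expect_true(f1$flags[[pr$probe_id[1]]])
  expect_equal(f1$n_flagged, sum(f1$flags))
  # a variant strictly inside one gap-fill may still sit under a
  # neighbouring tile's arm; pick a position clear of every arm span
  arm_pos <- unlist(lapply(seq_len(nrow(pr)), function(i)
    c(seq(pr$ext_start[i], pr$ext_end[i] - 1L),
      seq(pr$lig_start[i], pr$lig_end[i] - 1L))))
  inside <- setdiff(seq(pr$gapfill_start[5], pr$gapfill_end[5] - 1L),
                    arm_pos)[1]
  f2 <- flag_arm_variants(panel, data.frame(contig = pr$contig[5],
                                            pos = inside))
  expect_equal(f2$n_flagged, 0L)

  planted <- data.frame(contig = pr$contig[1:10], pos = pr$ext_start[1:10])
  f3 <- flag_arm_variants(panel, planted)
  expect_equal(f3$n_flagged, 10L)
  expect_named(f3$covariates,
               c("probe_id", "ext_tm", "ext_gc", "ext_l", "lig_tm",
                 "lig_gc", "lig_l", "arm_variant"))
  expect_warning(flag_arm_variants(panel,
                                   data.frame(contig = "nope", pos = 1L)),
                 "unknown contig")
})
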