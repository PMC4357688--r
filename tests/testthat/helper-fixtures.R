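# Shared fixtures, built in code and cached for the duration of a test run.

.fx <- new.env(parent = emptyenv())

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

fixture_genome <- function() {
  if (is.null(.fx$genome)) {
    set.seed(42)
    .fx$genome <- reference_genome(c(c1 = rand_dna(50000)))
  }
  .fx$genome
}

# 19-probe panel over one 1 kb region of the clean random genome
fixture_panel <- function() {
  if (is.null(.fx$panel)) {
    regions <- data.frame(contig = "c1", start = 1000L, end = 2000L)
    .fx$panel <- design_panel(regions, fixture_genome(), seed = 7)
  }
  .fx$panel
}

# Error-free simulated capture run through the full pipeline
fixture_pipeline_clean <- function() {
  if (is.null(.fx$clean)) {
    panel <- fixture_panel()
    sp <- sim_params(mean_events = 60, dup_mean = 1, error_rate = 0)
    sim <- simulate_capture_products(panel, fixture_genome(), NULL, sp,
                                     seed = 11)
    reads <- emit_read_pairs(sim, panel, sp, seed = 12)
    records <- process_read_pairs(reads, NULL, panel)
    .fx$clean <- list(panel = panel, sim = sim, reads = reads,
                      records = records)
  }
  .fx$clean
}

# Naive both-strand occurrence count: scan the genome and its reverse
# complement; a palindromic query sees the same duplex sites in both scans
# and is counted once.
naive_occurrences <- function(genome, query) {
  cnt <- function(s, q) {
    p <- gregexpr(paste0("(?=", q, ")"), s, perl = TRUE)[[1]]
    if (p[1] == -1L) 0L else length(p)
  }
  tot <- 0L
  for (s in genome$seq) {
    tot <- tot + cnt(s, query)
    if (revcomp(query) != query) tot <- tot + cnt(revcomp(s), query)
  }
  tot
}

write_temp_fasta <- function(seqs, width = 60L) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  close(con)
  path
}
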