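---
title: "Designing and analysing duplex-MIP capture panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing duplex-MIP capture panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmip)
```

## The capture chemistry being modelled

A molecular inversion probe (MIP) is an oligonucleotide whose two terminal
*annealing arms* hybridize on either side of a genomic target. Gap-filling
polymerization from the 3' *extension arm* across the target, followed by
ligation to the 5' *ligation arm*, circularizes the probe around a copy of the
target (the *gap-fill*). Circles are amplified and sequenced; each
circularization event is an independent capture of one template molecule.

`duplexmip` models the microarray-based duplex variant of this chemistry.
Probes are synthesized as double-stranded *precursor* oligos flanked by
amplification primer regions and two EarI cassettes; EarI is a type IIS
enzyme (recognition `CTCTTC`, cutting 1 nt downstream on the recognition
strand and 4 nt on the complement), so a single digestion releases the
functional probe from the amplified precursor. Because EarI must not cut
inside the probe, no arm may contain the recognition site on either strand.
Each probe backbone carries a 10-nt random *unique barcode* adjacent to the
extension arm; the (arm pair, barcode) key identifies independent
circularization events, which is what makes PCR duplicates removable.

## Panel design

### Tiling

Target regions are cut into 100-bp tiles stepped by 50 bp (2x tiling), so
interior bases are covered by two probes and a failed probe leaves no hole
that its neighbours cannot cover. The last tile is anchored to the region
end; regions shorter than 100 bp get one tile centered on the region,
extended symmetrically into flanking sequence so that short exons retain
their splice junctions.

### Arm geometry

For each side of a tile, 25 arm candidates are enumerated: five lengths
$\ell \in \{21,\dots,25\}$ crossed with five outward shifts
$s \in \{0,\dots,4\}$. The arm's inner edge sits

$$d = (25 - \ell) + s$$

bases outward from the tile boundary, and the arm extends a further $\ell$
bases outward. The gap-fill span is the tile expanded by $d_{ext}$ and
$d_{lig}$, so its length is $100 + d_{ext} + d_{lig}$ with
$d \in [0, 8]$ per side — exhaustive enumeration of the $25 \times 25$
geometry grid yields exactly the lengths 100–116. This inner-edge
parameterisation is the simplest geometry consistent with that attainable
range; it is a reconstruction (the five "shifts" admit other readings), and
it is isolated in `enumerate_arm_candidates()` should a different convention
ever be needed. Keeping the gap-fill inside a narrow 100–116 window controls
amplicon-length PCR bias downstream.

All arm metrics are computed on the Watson strand. Duplex probes present
both strands anyway, and scoring one strand keeps the design deterministic;
the complement is implicit and never separately scored.

### Filtering and selection

A candidate is excluded if it

* contains `CTCTTC` or `GAAGAG` (EarI would cut the probe);
* perfectly matches more than one genomic placement on either strand
  (capture would be ambiguous);
* contains a homopolymer run longer than 8 bases;
* has GC content below 10% or above 90%.

Each candidate carries all applicable flags, but category accounting
attributes an exclusion to the *first* failing criterion in the order above,
and a tile that loses all 25 candidates on a side is reported under the
majority category of that side (ties resolved in the same order). The
redundancy screen counts exact, full-length occurrences over both strands of
the reference (a palindromic arm matching one duplex site counts once);
exact counting implements the perfect-multi-alignment criterion directly and
reproducibly, with no alignment-tool heuristics.

Among survivors, selection is lexicographic: smallest $|T_m - 60\,°C|$,
then smallest $|GC - 50\%|$, then the longer arm, then the smaller shift.
The literature on this design style states only "closest to 60 °C and 50%";
the lexicographic order makes the preference deterministic, and the two
tie-breaks prefer arms that are physically more tolerant of single
mismatches (longer) and geometrically central (less shifted).

### Melting temperature

$T_m$ comes from the nearest-neighbor model with the unified
dinucleotide parameter set:

$$T_m = \frac{1000\,\Delta H^\circ}{\Delta S^\circ + 0.368\,(N-1)\ln[\mathrm{Na^+}] + R \ln(C_T/4)} - 273.15$$

with $\Delta H^\circ$ (kcal/mol) and $\Delta S^\circ$ (cal/mol·K) summed
over stacks plus terminal initiation terms, and the symmetry correction for
self-complementary sequences. The assay concentrations are not dictated by
the chemistry model itself, so they are explicit, swappable model
parameters: $C_T = 0.25\,\mu M$ total strand concentration and 50 mM
monovalent salt with the entropic salt correction — standard probe-design
conditions. Candidates containing N are discarded before scoring: there is
no defensible stacking value for an ambiguous base.

```{r thermo}
thermo_model()
melting_temp("ACGTACGTACGTACGTACGTA")
```

### Precursor assembly

The precursor top strand is

```
AmpF | spacer | CTCTTC | x1 | [lig arm | backbone | barcode | ext arm] | x4 | GAAGAG | spacer | AmpR
```

where `x1`/`x4` are the 1-nt and 4-nt cut offsets of the two EarI sites,
oriented so that the top-strand cuts land exactly at the probe's 5' and 3'
termini. Assembly is validated by *simulated digestion*
(`digest_earI()`): the released middle fragment must equal the probe top
strand, and the precursor must contain exactly one recognition placement per
strand. Junctions (or an unlucky barcode draw) can create a spurious
`CTCTTC`; in that case alternative spacers and fresh barcodes are tried
until digestion validates. Barcodes are i.i.d. uniform draws from a seeded
RNG; collisions between probes are permitted because the deduplication key
is (probe, barcode), not the barcode alone.

## Capture simulation

The simulator exists so the read processor can be tested against known
truth. It emulates, per probe: a lognormal abundance factor times a Poisson
event count (capture efficiency varies by orders of magnitude between
probes); a fresh 10-nt barcode per circularization event; allele choice at
planted heterozygous sites with probability 1/2; and `1 + Geometric(r)` PCR
copies per event, so the expected duplicate fraction has the closed form
$r/(1+r)$. Reads are emitted as paired FASTQ with the layout
`[AmpF][barcode][ext arm][gap-fill][lig arm][revcomp AmpR]`, R1 reading
forward from after AmpF and R2 reading back from before AmpR, with uniform
per-base substitution errors and Gaussian-jittered Phred qualities.

Default study conditions were fixed once from the statistical structure of
deep duplex-MIP capture experiments: `dup_mean = 2.45` (a ~71% average
duplicate fraction, since $r/(1+r) = 0.71$), `abundance_sdlog = 1.3`
(placing roughly 60% of probes within a 10-fold abundance window,
the scale reported for this probe chemistry), `abundance_meanlog`
$= -\sigma^2/2$ so the abundance factor has unit mean, 150-base reads,
$10^{-3}$ substitution errors around Q33.

What the simulator does **not** emulate: capture bias correlated with arm
Tm/GC (abundance dispersion is assigned at random, not mechanistically),
indels, adapter read-through, quality-by-cycle decay, off-target capture,
and chimeric PCR products. Tests passing on simulated data therefore
demonstrate the correctness of the bookkeeping — identification,
deduplication, accounting — not the biological fidelity of any abundance
model.

## Read processing

Identification anchors on layout: R1 carries the barcode in its first 10
bases followed by the extension arm; R2 begins with the
reverse-complemented ligation arm. Arms match with at most `max_mismatch`
errors per arm (default 1 — sequencing errors at $10^{-3}$ per base leave
~2–5% of pairs with an arm error, and one tolerated mismatch recovers
nearly all of them while keeping 21-mer arms unambiguous); a pair whose
best match is shared by two probes is flagged ambiguous and dropped rather
than guessed.

The gap-fill is merged from both mates. Its length is taken from the
identified probe and *verified* against the mate overlap; if the overlap
disagrees, nearby lengths (90–126) are scanned and the best-agreeing length
is used, so truncated molecules are measured rather than assumed. Pairs
whose measured gap-fill falls outside 100–116 are flagged invalid and
excluded from deduplication. In the overlap, the higher-quality base wins;
ties keep the R1 base.

Deduplication groups by (probe, barcode) and keeps the pair with the
highest representative score. The score is the sum of base qualities that
are at least Q15 over both mates — the Picard-style reading of
"highest sum of base quality scores ≥ 15"; a literal reading (plain sum) is
available via `score_mode = "total"`. Score ties break toward the
lexicographically smallest read id, and output is ordered by probe then
barcode, making the operation deterministic and idempotent. Deduplication
runs pre-alignment: the key and score depend only on read content, so the
result is identical to deduplicating after alignment, which stays out of
scope.

Two statistics need conventions the literature leaves open:

* **Percent unique at depth.** Unique-read percentage falls as depth rises,
  so conditions are compared after subsampling to a common read count
  (2 million by default): `percent_unique_at_depth()` draws a seeded
  uniform subsample and reports the percent of distinct (probe, barcode)
  keys within it.
* **Uniformity.** "Fraction of probes within an n-fold range" does not say
  where the range sits. The default slides a log10 window of width
  $\log_{10}(\mathrm{fold})$ over detected probes and reports the best
  covered fraction; a median-centered window is available via
  `method = "median_centered"`. The sliding window is the more charitable
  and scale-free of the two, and is monotone in the fold.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; BED on disk.
* Empty sequences are rejected by `gc_percent()` and
  `max_homopolymer_run()`; `melting_temp()` requires length ≥ 8 (shorter
  arms cannot occur) and refuses N.
* Regions whose tiles (plus the 33-base arm flank) would leave the contig
  are reported as failed regions, never as errors.
* `build_index()` accepts anchor lengths 1–21 (default 12); query
  correctness is independent of the anchor because matching is exact.
* All randomness (barcodes, simulation, subsampling) flows through explicit
  seeds; identical inputs and seed give byte-identical outputs.

## Problem sizes used by the test suite

The suite designs a 19-probe panel over a 1-kb region of a 50-kb synthetic
reference, processes roughly 10,000 simulated read pairs end to end
(error-free runs must recover the truth's distinct event count exactly),
and measures the duplicate fraction on ~50,000 simulated molecules at
geometric mean 1, where it must land within three binomial standard errors
of 1/2. These sizes exercise every code path of the design and processing
stack at a scale where the brute-force oracles (naive occurrence scans,
hash-grouping deduplication) are still exact and fast.

## Known limitations

* Extension and ligation arms are selected independently; a joint
  optimisation over arm pairs could trade Tm balance between sides.
* Common-SNP-aware arm design is not implemented; variants under arms are
  only flagged post hoc (`flag_arm_variants()`).
* The redundancy screen is exact-match only; near-matches that could
  cross-hybridize are not modelled.
* Alignment, indel realignment and genotype calling are out of scope; the
  processor exports deduplicated gap-fill FASTQ for external tools.
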