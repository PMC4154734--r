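---
title: "Models and methods in ddradkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ddradkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradkit)
```

This vignette explains the models behind `ddradkit`: what the digest
predictor, the read-processing rules, the clustering and genotyping
machinery, and the library simulator assume; which parameters matter and
why their defaults are what they are; and what the package's passing
tests do and do not demonstrate about real sequencing data.

## In silico digestion

A ddRAD locus is the interval from the first base of a rare-cutter
(SbfI, `CCTGCAGG`) recognition site to the last base of the nearest
frequent-cutter (EcoRI, `GAATTC`) site, with no site of either enzyme
strictly in between. All coordinates are 0-based, half-open, on the top
strand. Because sequencing reconstructs the full recognition sequences,
fragment boundaries are defined on recognition-site coordinates, not
cut offsets; the cut offsets in `restriction_enzymes()` are retained
for documentation only. Overlapping sites are legal — adjacent SbfI and
EcoRI sites sharing one base give the minimal reconstructible locus of
`8 + 6 - 1 = 13` bp — and only palindromic enzymes are supported, so a
single top-strand scan covers both strands; a non-palindromic enzyme
raises an explicit error rather than silently scanning one strand.
Minus-orientation loci (SbfI site rightmost) are reported
reverse-complemented so the SbfI site always leads, matching read
structure. Recognition sites never match across `N`; `gc_fraction()`
excludes `N` from its denominator and refuses all-`N` input, since a
GC value of 0 would be indistinguishable from an AT-rich sequence.

Single-copy annotation counts exact occurrences of each locus's leading
100-bp tag (or the whole sequence for shorter loci) on both genome
strands. This is a deterministic stand-in for a unique high-quality
alignment hit: on the synthetic genomes used in testing, exact tag
counting and alignment-based uniqueness coincide; on a real genome with
diverged repeats the exact criterion is the stricter of the two.

## Read processing

Demultiplexing is exact-match only. The barcode sets produced by
`generate_barcode_set()` guarantee pairwise Hamming distance ≥ 2, which
*detects* any single sequencing error but cannot correct it; tolerating
one mismatch would assign misread barcodes to the wrong sample, so
ambiguous reads go to the unassigned bin instead. The two bases
synthesized during site reconstruction (the `CC` prefix, and the
trailing `C` after adapter trimming) carry sentinel quality 40; they
are shared by every read at a locus and are therefore never variant
positions in practice.

Adapter trimming places the adapter prefix at every 3' start position
of the read and counts mismatches — the end-gap-free, unit-cost
alignment restricted to substitutions, which is adequate because
adapters are synthetic oligos where indel errors are negligible. The
defaults (`min_overlap = 8`, `max_err = 0.2`) are exposed in the
function signature; eight bases is the shortest overlap whose chance
match probability (4^-8) is negligible across a lane, and 20% mismatch
tolerance accepts two errors in a 10-base overlap without accepting
random sequence.

Concatemer screening runs after trimming: any complete internal SbfI
site marks a two-fragment chimera and discards the read, while the
first internal EcoRI site is the legitimate locus terminus and
truncates the read immediately after it. The EcoRI search starts at
read position 8 so the terminal site may overlap the final base of the
leading SbfI site — this is what lets the 13-bp minimal locus through.

## Clustering and alignment

Condensed reads pooled across samples are clustered greedily in
descending mean-quality order (ties: count, then sequence), each read
joining the first centroid at ≥ 85% identity. Identity is defined as
matching columns over alignment columns under an alignment with free
end gaps in which the shorter sequence must be fully aligned; this
accommodates the length differences produced by short adapter-trimmed
loci without rewarding spurious short overlaps. Two implementation
shortcuts keep this exact definition affordable: equal-length pairs
within 15% ungapped mismatches are accepted at their gapless identity
(their optimal alignment is gapless), and equal-length pairs below 50%
gapless identity are rejected without invoking the aligner — no
biologically meaningful gapped alignment rescues a same-length pair
that disagrees at more than half its positions. The affine-gap aligner
(match 1, mismatch −1, gap open 2, extend 1) handles everything else.

Mapped clusters whose best hits share contig and strand within ±50 bp
merge single-link (chained; `chain = FALSE` caps each merged group's
span instead). Chaining is the simplest closure of "approximately the
same position" and is what reunites alleles separated by a long indel,
which the identity threshold alone splits. The built-in mapper
escalates from exact matching through substitution-only and then
indel-tolerant matching, and falls back to a local alignment that must
cover at least 40% of the query — the fallback exists precisely for
long-indel alleles, and the coverage floor keeps random sequence
anonymous. Any function with the same signature can replace it.

Each cluster is aligned with a deterministic center-star procedure:
every member is pairwise-aligned to the highest-quality member and the
pairwise alignments are merged on centroid coordinates, taking the
maximum insertion width at each slot and right-padding shorter
insertions. Center-star is not guaranteed optimal in general, but
cluster members are ≥ 85% identical by construction, where it matches
the exhaustive optimum (the test suite checks this against a
brute-force three-sequence aligner).

## Genotyping

The caller works on haplotypes — each read's states across the variant
columns — rather than on isolated SNPs, and compares their per-sample
counts with Mendelian expectations. The decision bands follow the
fractions `f1 ≥ f2 ≥ f3` of the sample's top haplotypes, with
denominators over *all* the sample's reads at the locus:

| condition | call |
|---|---|
| `f2 > 0.29`, `f3 ≤ 0.10` | heterozygote |
| `f2 > 0.29`, `f3 > 0.10` | flagged: extra reads |
| `0.20 ≤ f2 ≤ 0.29`, both haplotypes elsewhere | provisional het, passed |
| `0.20 ≤ f2 ≤ 0.29`, otherwise | flagged: bad ratio |
| `0.07 ≤ f2 < 0.20` | flagged: bad ratio |
| `f2 < 0.07` (`f1 > 0.93`) | homozygote |

Band edges are pinned by tests at `f2` ∈ {0.069, 0.07, 0.20, 0.29,
0.291} and `f1` ∈ {0.93, 0.931}: the homozygote threshold is strict
("more than 93%"), the provisional band is inclusive on both ends, and
the bad-ratio band is `[0.07, 0.20)`. "Present in the population" for
provisional rescue means the haplotype has at least one read in at
least one other sample — the weakest reading, chosen because provisional
heterozygotes are exactly the cells where depth is too thin to demand
more. Homozygotes at variable loci need 5 reads; at invariant loci no
depth floor applies, because with one haplotype segregating there is
nothing to miscall. A variant column whose read-weighted mean quality
falls below Q25 truncates the locus at that column before calling.

Each unique indel — a maximal run of adjacent gap columns with
identical row support — is scored as one presence/absence character
regardless of length, so a 30-bp deletion is one character, not thirty.

Duplicate-locus screens exclude loci with more than two flagged
genotypes, unusually high mean depth (default ceiling 500 reads), a
one-sided exact-test heterozygote excess against Hardy–Weinberg
(Levene's conditional distribution, implemented directly), allele pairs
diverging at more than 10% of the locus, or heterozygote mean depth
more than twice homozygote mean depth. The depth ceiling, divergence
fraction and depth ratio are judgement calls exposed as parameters; the
published analyses these screens descend from do not quantify them.

One classification detail is resolved against the category definitions'
literal priority: a chimera-derived locus starts at an exact SbfI site
that also lacks a nearby EcoRI site, so testing "SbfI site without
nearby EcoRI" before "inside a predicted SbfI–SbfI fragment" would
leave the chimera category unreachable. `classify_recovered_loci()`
therefore tests SbfI–SbfI fragment membership first for exact-site
starts; the four categories remain mutually exclusive.

## The simulator

The simulator emulates the statistical structure the pipeline assumes,
not any particular sequencing chemistry.

**Genomes.** `make_toy_genome()` assembles planted features — in-range,
below-range and above-range SbfI–EcoRI fragments, near-canonical SbfI
sites with chosen mismatch positions, SbfI–SbfI fragments, duplicated
leading tags — separated by 600–800 bp spacers scrubbed of both
recognition sequences. Spacers that long guarantee no unplanned
in-range fragment can form between features (the fragment spanning a
spacer is at least `600 + 14` bp).

**Populations.** Each locus receives segregating SNPs at rate 0.013 per
interior site (so a ~100 bp read window carries ~1.3 polymorphisms,
matching the observed polymorphism density in the data this package
models) and short deletions at rate 0.0015 per site with lengths 1–4;
derived-allele counts follow the neutral `1/i` spectrum and carriers
are assigned to random chromosomes, which are then paired at random
(Hardy–Weinberg). With probability 0.02 a locus carries a
restriction-site polymorphism: carrier chromosomes are null and emit no
reads (a rate of 1 models a fixed site difference). Null alleles via
indels that move a fragment outside the size window arise for free from
the depth model.

**Depths.** In-window allele copies get weight
`exp(β_len (len − 253) + β_gc (gc − 0.5)) · taper(len)`, where the
taper rises linearly 0.5 → 1.0 across the 178–328 bp window (the
half-width/full-width tapered gel cut); below-window copies get a
single carryover weight (0.35) with a weaker GC coefficient (1.5),
reflecting that sub-range recovery is not strongly length-dependent;
above-window copies get zero. Each (individual, locus) draws one
negative-binomial total (dispersion 6) over the individual's
proportional read budget and splits it between the two allele copies
binomially by relative weight — so heterozygote allele-depth pairs are
`Binomial(depth, 1/2)` for equivalent alleles, which is the Mendelian
sampling law the QC tests verify. An earlier formulation drew per-allele
depths independently; it was replaced because independent draws
overdisperse allele balance relative to binomial sampling.

**Calibration.** `β_len = −0.011`/bp and `β_gc = 4.2` were fixed by a
one-time sweep so that regressing realized log depth on length and GC
over 2,000 surveyed in-range loci (`depth_bias_survey()`) yields
R² ≈ 0.43, the strength of the empirical depth–length–GC relationship
this simulator mirrors, with the length and GC partial contributions of
comparable size. The published partial R² values (0.20 and 0.23) are
mutually inconsistent with the published total under near-orthogonal
predictors, so the total is the calibration target and the split is
matched in ratio only.

**Artifacts.** Star reads are emitted per near-canonical site at
per-individual Poisson rates with an edge:internal ratio of 28.87:1,
so the expected fraction of star reads from edge-position (1 or 8)
mismatches is 0.906 when sites are planted uniformly across positions.
The ligated overhang is regenerated as canonical sequence, so the
mismatch is visible only in the genome — exactly how star loci are
detected in practice (by mapping and inspecting the genomic 8-mer).
Chimera reads start inside an SbfI–SbfI fragment and run across the
reconstituted SbfI junction into a genuine fragment; when the junction
falls inside the read the processing stage discards it, and when it
falls beyond the read the locus survives to be caught by
classification — both fates are intended and tested.

**Reads.** Reads are `barcode + fragment` from recognition position 3
(the ligation overhang), 100 bp total; fragments shorter than the read
capacity continue through `...GAATT` into the P2 adapter. Errors flip
bases at the configured rate with low quality scores (Q3–Q20); correct
bases draw from a high-quality distribution peaked at Q37–Q40. Every
read is logged in a provenance table, so truth is available per read,
per allele, per cell.

## Statistical QC

The allele-balance test is the exact two-sided binomial test
(`stats::binom.test`), not a normal approximation, because per-allele
depths are routinely below 20. Exact tests are conservative at
moderate depth (true rejection rate ≈ 0.039 at depth 40 and nominal
0.05), which is why the rejection-rate check is run at a sample size
(300 heterozygotes) where the sampling band around 0.05 absorbs that
conservatism. Depth variance components come from a two-way ANOVA
without interaction (one observation per cell), reported as partial
η² = SS_effect / (SS_effect + SS_residual). The site-frequency-spectrum
expectation is the constant-size neutral `1/i`, normalized over the
spectrum's frequency classes; folding collapses class `i` with
`2n − i`.

## Problem sizes, determinism, and limitations

The test suite and examples run everything at desk scale: toy genomes
of ~15–25 kb with 8–24 planted in-range loci, 8–20 diploid individuals,
600–1,500 reads per individual, and 2,000 loci for the depth-regression
survey. These sizes were chosen so that every stage — including the
end-to-end concordance checks (exact agreement at zero error with
per-allele depth ≥ 10; ≥ 99.5% agreement at 0.1% per-base error with
per-allele depth ≥ 20) — exercises the same code paths as a full-size
run while remaining reproducible from fixed seeds in minutes. All
randomness flows through explicit seeds; identical seeds give
byte-identical FASTQ.

What passing tests do **not** show: the simulator draws errors
independently per base (no machine-specific error profiles, no
PCR-cycle-explicit amplification, no paired-end structure); its genomes
have no repeat families beyond the planted duplications; and the
built-in mapper is exact-match-based rather than a full local aligner,
so mapping sensitivity on diverged real genomes is understated.
Restriction-site polymorphism is modelled as a locus-level event rather
than per-base mutation of the recognition sequence, and insertions are
not simulated (deletions only). Real libraries also vary in depth
between samples for reasons (DNA quality, quantification error) the
per-individual read budget does not capture.
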