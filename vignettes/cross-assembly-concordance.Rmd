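---
title: "Cross-assembly SNV concordance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-assembly SNV concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When two versions of a reference genome are in active use (for the human
genome, GRCh37-era and GRCh38-era assemblies), variant calls made against
one version must often be translated to the coordinate system of the other.
The translation — *liftover* — walks a precomputed whole-genome alignment
stored as a UCSC chain file. Liftover can fail (the position falls in
sequence absent from the other assembly), and even when it succeeds the
lifted call may disagree with what a caller finds when the same reads are
aligned directly to the target assembly. `refconcord` implements the full
accounting of this process: how many SNVs convert, how the converted calls
partition into concordant and discordant classes, and what distinguishes
the discordant ones.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` drive a complete run (simulate → validate liftover →
compare → characterize) and write their tables under `results/`, while all
computation lives in the package functions so that the test suite and
`scripts/acceptance.R` exercise exactly the same code.

## Statistics computed

For a source call set of $N$ biallelic SNVs, of which $N_c$ lift
successfully, the *conversion rate* is

$$CR = 100 \cdot N_c / N.$$

Each converted SNV is compared with the call set obtained directly on the
target assembly, keyed by (sequence, position, reference allele):

* **concordant** — a direct call exists at the key with the same unordered
  diploid allele pair;
* **genotype discordant (GD)** — the key matches but the alternate allele
  or the genotype differs;
* **position discordant (PD)** — no direct call exists at the key.

The discordance rates are percentages of the converted calls,
$PDR = 100 \cdot n_{PD}/N_c$ and $GDR = 100 \cdot n_{GD}/N_c$, and
$\log_2(n_{PD}/n_{GD})$ summarises their balance.

With converted calls split by membership in high-confidence (HC) versus
low-confidence (LC) regions, the enrichment of discordance in LC sequence
is

$$PR = \frac{n^{LC}_{PD}/n^{LC}}{n^{HC}_{PD}/n^{HC}}, \qquad
  GR = \frac{n^{LC}_{GD}/n^{LC}}{n^{HC}_{GD}/n^{HC}},$$

reported as $\log_2$ values. Discordant rosters are additionally profiled
by read depth (frequency tables per depth with overflow and missing bins)
and by reference-allele base composition (percent A/T/G/C and combined
G+C).

## Liftover semantics

Chain files are parsed bit-exactly per the UCSC format. One convention
deserves emphasis: following `liftOver` usage, the chain's *t*-side is
treated as the lift **source** and the *q*-side as the lift **target**. All
internal coordinates are 0-based half-open; VCF's 1-based positions are
converted only at the I/O boundary, and the target side of a chain is
strand-local, so on a `-` block the plus-strand coordinate is
`target_size - 1 - local`.

Point mapping resolves each query to exactly one outcome. Failure modes are
statuses, never exceptions: a position inside a chain's span but between
aligned blocks is `unmapped_in_gap`; a position no chain covers is
`unmapped_no_chain`. When several chains cover a position, the
highest-score chain wins; equal-score chains that disagree on the target
yield `rejected_multimap`. Alleles lift unchanged on `+` blocks and are
complemented on `-` blocks; the lifted reference allele is then checked
against the target assembly base. A mismatch is rejected by default
(`on_ref_mismatch = "reject"`), the behaviour of Picard's LiftoverVcf; the
`"keep"` setting exists because conversion tools differ here and the choice
measurably affects conversion rates, so it should be an explicit knob
rather than an implicit behaviour. The test suite cross-checks the whole
mapping path against `rtracklayer::liftOver` on written chain files, an
implementation developed independently of this one.

Genotype strings travel through liftover verbatim (apart from allele
complementation), preserving phase separators: liftover must not alter
zygosity. Converted output is re-sorted by target coordinate, since block
permutations and inversions can reorder records.

## Call-set filtering

Only biallelic single-nucleotide substitutions enter the comparison.
Indels, symbolic/structural alleles and records with missing genotypes are
removed and tallied by class. Multi-allelic records are split per alternate
allele, each split keeping the sample's dosage of that allele (dosage 1 →
`0/1`, dosage 2 → `1/1`); alleles the sample does not carry are dropped.
When two distinct input records share a position, the first after sorting
is kept — but split rows of a single multi-allelic record all survive.
Genotype comparison is phase-insensitive (unordered allele multiset),
because callers disagree on phasing far more often than on zygosity. An
alternate-allele mismatch at a matched position counts as genotype
discordance by default; `alt_mismatch_class = "position"` reclassifies it,
since reasonable pipelines have read this situation either way.

## The synthetic-data generator

The generator exists so that every statistic above has an exact or
closed-form expected value. It emulates, at desk scale, the situation the
pipeline is built for: two assembly versions that differ by structural
edits, and two call sets that disagree in controlled ways.

* **Assembly pair.** A random genome (default 42% GC, matching the human
  genome background) is edited with non-overlapping deletions, insertions
  and inversions. The base-level truth map produced alongside is the
  central oracle: the chain files for both directions are derived from it
  (colinear runs become one gapped `+` chain; each inversion becomes its
  own `-` chain, as in real chain files), and the tests require exhaustive
  agreement between chain-based mapping and the truth map at every base.
* **Call sets.** Variants are drawn at distinct positions; the direct
  target call set is the truth-mapped projection of the convertible
  variants, minus the injected position-discordant omissions, with
  genotype-discordant zygosity flips applied. Optionally, variants are
  placed in deleted regions (unconvertible by construction) and in
  target-inserted regions (target-private, unconvertible in the reverse
  direction) — the latter two reproduce directional conversion-rate
  asymmetry exactly by construction.
* **Injected biases.** Depths are negative binomial (mean 30, dispersion
  size 8 — a realistic WGS-like overdispersed profile), scaled by
  `depth_shift` (default 0.2) for unconvertible and discordant variants.
  Discordant reference alleles are drawn with combined G+C probability 0.52
  against the 0.42 background; the multinomial draw makes the realised
  composition exactly binomial around the target, so recovery tests can use
  standard confidence intervals. HC regions are random 1 kb windows
  covering a set fraction (default 70%) of each assembly, and injected
  discordances are drawn with per-position weight `lc_enrichment` in LC
  sequence, which makes the expected PR equal `lc_enrichment` exactly.
* **Determinism.** All randomness flows through the two seeds in
  `edit_spec()` and `discordance_spec()`; the same seeds give
  byte-identical fixture trees (no timestamps anywhere in the writers).

What the generator does *not* emulate: read-level error, repeats and
segmental duplications, aligner- or caller-specific error profiles, and
multi-sample genotyping. Passing tests therefore demonstrate that the
accounting — conversion, classification, stratification, composition — is
exact, not that any particular real pipeline pair will show a particular
discordance level.

## Numerical and sizing choices

* Rates are percentages; machine outputs carry full precision and text
  reports round to 2–3 decimals.
* PR/GR with a zero count anywhere are reported as `NA` sentinels and
  excluded from aggregates, as is $\log_2(n_{PD}/n_{GD})$ when either
  count is zero.
* The PR-recovery calibration uses 1.5 million variants with 10,000
  injected PD draws. The injected fraction must be small for the estimator
  to be unbiased — PD calls are part of the "all converted" denominator, so
  a large injected fraction drags the LC share of the denominator toward
  the enriched draw and shrinks PR below the true factor. At 0.67%
  injected, the bias is about 0.02 on the $\log_2$ scale against a
  sampling standard error of about 0.035.
* Composition recovery uses 20,000 discordant draws (99% binomial CI of
  ±0.9 percentage points on G+C); the depth contrast uses 5,000 converted
  against 1,000 unconvertible variants. The main worked fixture is a 150 kb
  genome with 10,000 variants; the exhaustive mapping oracle runs on twenty
  10–100 kb pairs.
* Base composition of discordant rosters is computed over the lifted
  (target-side) reference alleles. Whether to use the source- or
  target-side allele is a genuine choice; complementation on inverted
  blocks swaps A↔T and G↔C, so the combined G+C figure — the quantity of
  interest — is identical either way.

## Known limitations

Only SNVs are lifted and compared; indels and structural variants are out
of scope by design (their representation is not stable enough across
assemblies for position-keyed comparison). Single-sample call sets only.
Chain generation from whole-genome alignment is not provided — chains are
either supplied or derived from the generator's truth map. The HC/LC
stratifier consumes BED intervals; per-variant confidence tags must be
converted to regions first.
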