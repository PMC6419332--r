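# refconcord

Cross-assembly SNV liftover and concordance analysis.

When variant calls exist against two versions of a reference genome, two
questions decide whether results can be translated between them: how many
SNVs *convert* (lift to the other coordinate system through UCSC chain
files), and how many of the converted calls *agree* with what a caller
finds directly on the target assembly. `refconcord` implements both sides
of that accounting for anyone comparing call sets across assembly versions:
a chain-file liftover engine with allele-level checks, a concordance
classifier, and a characterization layer that profiles discordant SNVs by
confidence stratum, read depth and reference-allele base composition. A
seeded synthetic-data generator produces assembly pairs with known ground
truth so that every statistic has an exact expected value.

## The statistics

For a source call set of `N` biallelic SNVs with `N_c` successful
conversions, the conversion rate is `CR = 100 * N_c / N`. Each converted
SNV is matched against the direct target call set on the key
(sequence, position, ref):

- **concordant** — direct call with the same unordered diploid allele pair;
- **genotype discordant (GD)** — key matches, alt allele or genotype differs;
- **position discordant (PD)** — no direct call at the key.

`PDR = 100 * n_PD / N_c`, `GDR = 100 * n_GD / N_c`. With converted SNVs
stratified into high-confidence (HC) and low-confidence (LC) regions, the
LC enrichment of discordance is

    PR = (n_PD^LC / n^LC) / (n_PD^HC / n^HC)      (GR analogously for GD)

reported as log2 values, alongside per-depth frequency tables and the
A/T/G/C (and combined G+C) composition of discordant reference alleles.

## Worked example

The `analysis/` scripts run the whole study end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # fixture with known truth
Rscript analysis/02_liftover_validation.R  # exhaustive mapping + round trip
Rscript analysis/03_concordance.R          # bidirectional comparison
Rscript analysis/04_characterization.R     # PR/GR, depth, composition
```

The fixture is a 150 kb assembly pair (3 deletions, 2 insertions,
2 inversions) carrying 10,000 SNVs: 50 placed in deleted regions, 120
injected as position discordant and 35 as genotype discordant with an 8x
LC enrichment, plus 96 target-private variants in inserted sequence.
`analysis/03_concordance.R` prints:

```
      direction    run n_source n_converted conversion_rate_pct pdr_pct
1: asmA_to_asmB   run1    10000        9950            99.50000 1.20603
2: asmB_to_asmA   run1     9926        9830            99.03284 0.00000

forward: CR 99.50%, PDR 1.206%, GDR 0.352%, log2(PD/GD) 1.778
```

Reading: 50 of 10,000 source SNVs sit in deleted sequence, so the forward
conversion rate is exactly 99.50%; the 120 injected PD and 35 GD variants
are recovered exactly as `PDR = 100*120/9950` and `GDR = 100*35/9950`. The
reverse direction loses only the 96 target-private variants (CR 99.03%)
and shows zero PD — every direct-set variant exists in the source set.
`analysis/04_characterization.R` then prints:

```
  log2 PR = 3.205 (injected LC enrichment 8x -> expected ~3)
mean depth: converted 29.1 vs unconverted 6.2
```

matching the constructed biases (log2 8 = 3; unconvertible depths drawn at
0.2x the mean of 30).

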