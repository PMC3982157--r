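# disptm

Proteome-wide analysis of the relationship between intrinsic protein
disorder and predicted post-translational modification (PTM) sites, aimed
at plant proteomes.

Many PTMs — phosphorylation of Ser/Thr/Tyr, Lys acetylation, plant-specific
hydroxyproline O-glycosylation — are written by enzymes that prefer
flexible, surface-accessible substrate, so their predicted sites tend to
concentrate in intrinsically disordered regions (IDRs); methylation shows
the opposite tendency, and the N-glycosylation sequon (attached
co-translationally) little preference at all. `disptm` provides the full
desk-side machinery to quantify these effects for anyone with a proteome
FASTA, per-residue disorder annotations (RONN/POODLE/DISOPRED-style) and
PTM site tables (Musite/PAIL/PMeS-style), plus a synthetic proteome
generator so every statistic can be validated against planted ground
truth.

## The statistics at its core

**Disorder-to-order enrichment ratio.** With `Nd`, `No` the number of
predicted sites of one PTM type falling in disordered vs ordered residues,
and `Ld`, `Lo` the residue totals of the two proteome segments,

```
Rd/o = (Nd / Ld) / (No / Lo)
```

equals 1 when a PTM is indifferent to structure, >1 when it prefers
disordered sequence, <1 when it prefers ordered sequence.

**Site-count binning and significance.** Proteins are grouped by their
predicted site count (0, 1, …, ≥k; k = 4 conventionally, 7 for
methylation), each bin summarised by its mean per-protein disorder
fraction, and the bin ordinal correlated with the bin mean via Pearson's
r. Significance is the one-tailed probability of `t = r·sqrt((n−2)/(1−r²))`
under Student's t with `n − 2` degrees of freedom, `n` being the number of
populated bins.

**Motif scanners.** N-glycosylation sequon `N-X-[S/T]` (X ≠ Pro) with all
overlapping occurrences reported; plant O-glycosylation consensus
`[A/S/T/V]-P(1,4)-X(0-10)-[A/S/T/V]-P(1,4)` matched leftmost,
non-overlapping, lazy, with the countable site anchored at the first Pro
of the second Pro run.

Dataset construction (length filter to [50, 2000] aa, greedy redundancy
reduction at 90 % global identity), normalised PTM contents (sites per 400
residues), monocot/dicot contrasts and a pipeline driver with TSV outputs
round out the toolkit. File formats are documented in
[`inst/FORMATS.md`](inst/FORMATS.md).

## Worked example

```r
library(disptm)

sim <- generate_proteome(synth_config(
  n_proteins = 300, ptm_rates = c(pSer = 0.08),
  enrichment = c(pSer = 3), seed = 42))

compute_rdo(sim$sites, sim$profiles, "pSer")$rdo
#> [1] 2.976
```

Sites were planted 3× denser in disordered residues; from 782 sites over
120 000 residues the pipeline estimates Rd/o = 2.976. The bin table and
its correlation:

```r
bins <- bin_by_site_count(sim$sites, sim$profiles, "pSer", 4)
bins[, c("bin_label", "n_proteins", "mean_disorder")]
#>   bin_label n_proteins mean_disorder
#> 1         0         30         0.251
#> 2         1         52         0.264
#> 3         2         78         0.273
#> 4         3         56         0.318
#> 5       >=4         84         0.356
correlate_bins(bins)[c("r", "p_one_tailed")]
#> $r            [1] 0.9570
#> $p_one_tailed [1] 0.00531
```

Mean disorder rises monotonically with site count (r = 0.957, one-tailed
p = 0.0053 over the 5 bins), recovering the planted preference. The same
significance routine reproduces published desk values, e.g.

```r
round(one_tailed_p(0.996, 5), 4)
#> [1] 2e-04
```

A command-line wrapper with `filter`, `scan`, `disorder-stats`,
`ptm-stats`, `correlate`, `simulate` and `run-all` subcommands lives at
`system.file("cli", "disptm.R", package = "disptm")`.

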