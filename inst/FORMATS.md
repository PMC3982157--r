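# disptm file formats

All tabular files are TSV with a header line; floating-point values are
written with 4 decimal places; positions are 1-based and inclusive.

## FASTA
Standard multi-line FASTA. The record id is the header token before the
first whitespace. Sequences are upper-cased on read; a terminal `*` is
stripped. Allowed characters: the 20 standard one-letter amino-acid codes
plus `X`.

## Disorder TSV
Columns: `protein_id`, `position`, `score` (in [0,1]) and/or `call`
(`1`/`0`). Positions must be contiguous `1..L` for each protein. When
`call` is absent it is derived as `score >= threshold` (default 0.5,
boundary inclusive).

## Site TSV
Columns: `protein_id`, `position`, `residue`, `ptm_type`. Types:
`pSer`, `pThr`, `pTyr`, `O-gly`, `N-gly`, `K-ace`, `K-met`, `R-met`;
the residue column must be compatible with the type (S, T, Y, P, N, K, K,
R respectively) and, when a proteome is available, with the sequence.

## Species manifest (YAML)
```yaml
species:
  <name>:
    category: monocot | dicot
    fasta: <path>
    disorder: <path>
    sites:              # optional; O-gly/N-gly fall back to motif scanning
      pSer: <path>
```
Relative paths resolve against the manifest's directory.

## Pipeline outputs (`run_all` with `out_dir`)
- `<species>_disorder_summary.tsv`: `protein_id`, `L`, `Ld`, `fraction`.
- `<species>_ptm_stats.tsv`: per PTM type `total_sites`, `per_400`, `Nd`,
  `No`, `Ld`, `Lo`, `rdo`, `r`, `p_one_tailed`.
- `<species>_bins.tsv`: `ptm_type`, `bin_index`, `bin_label`, `k_max`,
  `n_proteins`, `mean_disorder`.
- `table1_like.tsv`: species-by-PTM grid, one `r` row (3 decimals) above
  one `p` row (4 decimals, `<0.0001` floor) per species.
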