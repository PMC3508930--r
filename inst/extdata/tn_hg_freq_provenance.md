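# Provenance of the Tamil Nadu haplogroup frequency fixture

`tn_hg_freq.csv` holds the published haplogroup frequency table (percent) for
the 31 endogamous Tamil Nadu populations (N = 1680 Y chromosomes, 21
haplogroups), as transcribed from the printed source table, together with the
published per-population Nei gene diversity and its standard deviation.

## Column displacement in the source transcription

In the machine-extracted source table every population row prints 20 haplogroup
values inline, then the gene-diversity column, then **one trailing haplogroup
value**. The trailing value is the J2-M172 column for every row: inline values
1-9 are C-M130 … J-M304, the trailing value is J2-M172, and inline values 10-20
are J2a1-M47 … R2-M124. The grand-total row is printed undisplaced and anchors
the resolution.

Checks that confirm this mapping (all performed programmatically and re-run by
the package test suite):

- every one of the 31 reconstructed count rows sums exactly to its printed N
  (rounding percent x N / 100 to the nearest integer, ties to even);
- pooled member-row frequencies reproduce all seven printed group-total rows to
  within 0.005 percentage points in every cell;
- pooled counts over all 31 rows reproduce the printed undisplaced total row
  exactly at two decimals in every cell, including J2-M172 = 157/1680 = 9.35%,
  K-M9 = 13/1680 = 0.77% and L1-M27 = 235/1680 = 13.99% (235 matches the
  number of L1 chromosomes quoted for the L1 network figure);
- the reconstructed C-M130 total is 74 chromosomes, as printed in the text.

No residual ambiguity remains under this mapping.

## Files

- `tn_hg_freq.csv` — per-population frequencies (percent), curated column order.
- `tn_hg_freq_groups.csv` — printed group-total rows (used for validation only).
- `tn_hg_freq_total.csv` — printed grand-total row (used for validation only).
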