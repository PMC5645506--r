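# Packaged worked-example records

- `lipid_eqtl_records.tsv` — published tissue-specific eQTL effect slopes for
  lipid-metabolism genes mapped from type 2 diabetes and obesity GWAS SNPs,
  in tidy long form (one row per SNP x gene x tissue effect).  `low_rpkm`
  flags effects whose gene fell below the RPKM > 1.0 expression filter in
  that tissue.
- `igf2bp2_trans_records.tsv` — the three published tissue-specific
  trans-acting eQTL records anchored in the fine-mapped IGF2BP2 region on
  chromosome 3.  Gene coordinates, tissues, p-values, q-values and cell
  lines are the published values; the published records do not include SNP
  base positions, so `snp_pos_approx` holds synthetic placements inside the
  fine-mapped region (the cis/trans call for these records depends only on
  the chromosomes, so the exact positions are immaterial).
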