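{
  "founders": { "n_snps": 2000, "n_chromosomes": 20, "maf_range": [0.1, 0.5], "chrom_length_cM": 75 },
  "design": {
    "generation_labels": [4, 5, 7, 8, 9, 11],
    "generation_sizes": [97, 48, 200, 184, 99, 197]
  },
  "crossover_rate": 1,
  "missing_rate": 0.01,
  "traits": {
    "poly": { "n_additive_qtl": 1000, "h2_additive": 0.4 },
    "epi":  { "n_additive_qtl": 100, "n_epistatic_pairs": 10,
              "h2_additive": 0.4, "epistatic_fraction": 0.4 }
  }
}
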