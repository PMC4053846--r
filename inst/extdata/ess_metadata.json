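{
  "description": "Published dataset sizes accompanying the packaged conserved-site table (synthetic data are generated in code; these are the printed sizes of the original merged candidate datasets).",
  "human_total_sites": 1432744,
  "human_total_sites_alternate": 1432743,
  "human_nonalu_sites": 52312,
  "mouse_total_sites": 10210,
  "snp_control": {
    "human_chrX_snps": 443366,
    "mouse_chrX_snps": 453726,
    "normalized_conserved_snps": 1.8,
    "signal_to_noise_at_least": 32
  },
  "conserved_sites": 59
}
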