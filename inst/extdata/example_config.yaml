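# Example screening configuration. Unset keys keep package defaults.
depth_min: 10
gq_min: 20
vaf_threshold: 0.35
qd_threshold: 12
loh_min_variants: 100
loh_min_fraction: 0.95
bin_size: 10000
inputs:
  vcf: family.vcf
  pedigree: pedigree.tsv
  annotations: annotations.tsv
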