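# Example synthetic-population specification: two groups of samples, two
# planted TE families with group-stratified allele frequencies, and an ERV
# family planted as solo LTRs plus a few full-length LTR-INT-LTR loci.
families:
  - name: SINE_like
    modal_length: 246
    length_jitter_sd: 3
    per_copy_divergence: 0.02
    n_loci: 20
    group_af: {A: 0.7, B: 0.3}
  - name: LINE_like
    modal_length: 6400
    length_jitter_sd: 10
    per_copy_divergence: 0.02
    n_loci: 10
    group_af: {A: 0.5, B: 0.5}
groups: {A: 10, B: 10}
erv:
  ltr_length: 1374
  internal_length: 4450
  n_full: 4
  n_solo: 30
  af: 0.5
  p_full: 0.5
background_rate: 100
min_spacing: 25000
contigs: {chr1: 3.0e8, chr2: 3.0e8}
seed: 42
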