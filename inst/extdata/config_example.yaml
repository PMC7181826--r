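# Example pipeline configuration (all keys optional; defaults shown by
# dripdsb::default_config()).  With simulate.enabled the input paths are
# ignored and a synthetic paired experiment is generated first.
paths:
  output_dir: dripdsb_out
parameters:
  half_width: 10000        # 20-kb break-centered window, 1-nt resolution
  pseudocount: 1           # reads added before library normalization
  score_half_width: 500    # 1-kb induction-score region
  metagene_smooth: 200     # nt moving average for metagenes
  heatmap_bin: 200         # nt bins for the heatmap matrix
  browser_half_width: 100000  # 200-kb browser window
  browser_smooth: 500
  browser_bin: 200
  split_mode: median_split
  alternatives:
    activity: greater
    pathway: two.sided
    genic: two.sided
simulate:
  enabled: true
  n_sites: 99
seed: 1
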