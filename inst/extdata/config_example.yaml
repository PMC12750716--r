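# Example run configuration. All keys are optional except paths$data
# (and paths$dag unless `adjustment` is given explicitly).
paths:
  data: cohort.csv            # participant-level CSV (raw or derived)
  dag: dag_reconstructed.txt  # causal DAG edge list with role lines
  out: gcompmed-results       # output directory for the result bundle

# map standard variable names to the CSV's column names (optional)
column_map: {}
#  x_helpful: nurse_always_helpful

mediator_scale: binary        # binary (high/low split) or raw (score)
m_binary_family: linear_probability  # or binomial
bses_threshold: 56            # high/low split point for the BSES total
hlq_cut: 2.5                  # HLQ scale high/low cut on the item mean

mc_draws: 100                 # mediator simulations per record
bootstrap_B: 1000             # bootstrap resamples
seed: 1
ci_level: 0.95
subsample: first_visit        # or repeat_visit (sensitivity re-run)
interaction: false            # exposure-by-mediator term in Y-equation
draw_y: false                 # draw Bernoulli outcomes instead of
                              # averaging predicted probabilities
write_replicates: false       # also write raw bootstrap replicates
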