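# Default configuration of the adheretraj pipeline.
# Every key is optional; omitted keys fall back to the package defaults
# shown here. Dates are ISO-8601.

# ---- simulation -----------------------------------------------------------
simulate: true          # false: read registry/dispensings/events CSVs
input_dir: null         # directory with the three input CSVs when simulate=false
n_subjects: 1000
seed: 1
T_months: 36            # 60 for the 5-year secondary analysis
mode: exact             # exact: dispensings realize each subject's target
                        # curve up to whole-day rounding; noisy: fixed pack
                        # sizes with jittered refill timing
noise_sd: 0.30          # extra month-level logit jitter (noisy mode only)

# latent trajectory-class mixture (high / medium / low)
class_weights:
  high: 0.19
  medium: 0.46
  low: 0.35

# probability that a subject violates exactly one cohort rule
distractor_rates:
  washout: 0.02
  lookback: 0.02
  followup: 0.02
  non_ibd: 0.02

# per-class probability of a biologic switch during follow-up
switch_probs:
  high: 0.326
  medium: 0.455
  low: 0.258

# ---- analysis -------------------------------------------------------------
k_range: [2, 10]        # candidate numbers of clusters
forced_k: null          # clinical-plausibility override of the voted k
stepwise: false         # stepwise AIC selection in the determinants model
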