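seed: 42

simulate:
  params: {lam: 2.83e-5, alpha: 1.0, p: 0.3, "N": 100000}
  init: {S: 99990, R: 10, I: 0}
  t_max: 60
  step: 1

synth:
  n_messages: 400
  date_range: ["2020-09-01", "2020-09-30"]
  price_mix: [0.3, 0.5, 0.2]
  sentiment_mix: [0.477, 0.204, 0.319]
  irony_rate: 0.0
  vaccine_type_probs: [0.5, 0.2, 0.1, 0.1, 0.1]
  price_lexicon: price_lexicon_synthetic.tsv
  sentiment_lexicon: sentiment_lexicon_synthetic.tsv
  reading: {lam: 2.83e-5, alpha: 1.0, p: 0.3, "N": 100000, R_init: 10, n_days: 60}

score_price:
  weighting: none
  normalize: true

fit:
  "N": 100000
  n_starts: 8
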