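{
  "N": 1000,
  "lambda_R": 3.0,
  "delta_R": 0.0,
  "lambda_A": 0.0,
  "delta_A": 1.5,
  "beta": 1.5,
  "alpha": 1.0,
  "nu": 1.0,
  "chi": 0.0,
  "eta": 0.0
}
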