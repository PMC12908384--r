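{
  "comment": "Across-replicate mean parameter estimates for the four treatment arms of the co-culture assay (12-replicate staged fit). Rates per hour, capacities in 1e5 cells. 'fixed' lists parameters frozen during fitting.",
  "UT": {
    "r_S": 0.032, "r_R": 0.0357, "r_N": 0,
    "K_S": 1.27, "K_R": 0.779, "K_N": 1,
    "alpha_SR": 1.54, "alpha_RS": 0.3,
    "lambda_SN": 0, "lambda_RN": 0,
    "fixed": ["r_N", "K_N", "lambda_SN", "lambda_RN"]
  },
  "NK": {
    "r_S": 0.034, "r_R": 0.0438, "r_N": 0.0178,
    "K_S": 1.27, "K_R": 0.779, "K_N": 1,
    "alpha_SR": 1.38, "alpha_RS": 0.0526,
    "lambda_SN": 0.0308, "lambda_RN": 0.0558,
    "fixed": ["K_S", "K_R", "K_N"]
  },
  "RT": {
    "r_S": 0.0162, "r_R": 0.0218, "r_N": 0,
    "K_S": 1.27, "K_R": 0.779, "K_N": 1,
    "alpha_SR": 2.36, "alpha_RS": 0.99,
    "lambda_SN": 0, "lambda_RN": 0,
    "fixed": ["r_N", "K_S", "K_R", "K_N", "lambda_SN", "lambda_RN"]
  },
  "RTNK": {
    "r_S": 0.023, "r_R": 0.0331, "r_N": 0.0245,
    "K_S": 1.27, "K_R": 0.779, "K_N": 1,
    "alpha_SR": 1.96, "alpha_RS": 1.83,
    "lambda_SN": 0.0865, "lambda_RN": 0.0945,
    "fixed": ["K_S", "K_R", "K_N"]
  }
}
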