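{
  "provenance": "Package defaults in the CHESHIRE-repository convention (sigma = intercept + slope * delta, slope negative) for GIAO mPW1PW91/6-311+G(d,p) shieldings with PCM chloroform. Verify or replace with the current entries from the Cheshire Chemical Shift Repository (http://cheshirenmr.info) for your exact level of theory.",
  "C": { "slope": -1.0522, "intercept": 186.5242 },
  "H": { "slope": -1.0936, "intercept": 31.8018 }
}
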