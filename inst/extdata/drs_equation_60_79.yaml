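# Dementia Risk Score, 60-79 age band, as published.
age_band: "60_79"
baseline_survival: 0.9969
centering:
  age: 65.608
  bmi: 27.501
  year: 2003.719
coefficients:
  age: 0.20921
  age_sq: -0.00339
  bmi: -0.0616
  bmi_sq: 0.002508
  female: 0.12854
  hypertension: 0.13199
  year: 0.04477
  depq2: 0.013371
  depq3: 0.117904
  depq4: 0.201776
  depq5: 0.225529
  smoke_former: -0.06792
  smoke_current: -0.08657
  heavy_drinking: 0.443535
  depression: 0.833612
  aspirin: 0.252833
  stroke_tia: 0.577207
  af: 0.220728
  diabetes: 0.286701
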