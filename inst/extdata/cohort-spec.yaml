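# Cohort-simulation profile for `tilquant.R simulate-cohort`
# (see cohortSpec for the full argument list).
nPatients: 87
tilMean:
  low: 6.0
  high: 25.0
tilDispersion: 3.0
pHigh: 0.5
baselineHazard: 0.012
hazardRatio: 0.3
censoringRate: 0.3
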