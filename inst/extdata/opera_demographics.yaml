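# Baseline demographic distributions for the ocrelizumab-trial-like cohort
# (about one quarter USA, remainder rest-of-world); editable.
age: {mean: 37.2, sd: 9.2, min: 18, max: 55}
sexFemale: 0.66
weight: {mean: 74.0, sd: 17.0, min: 40, max: 130}
race: {white: 0.90, other: 0.10}
# baseline disease activity (prior-year relapse frequency) relative
# to the cladribine-trial population
ebvRateScale: 1.5
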