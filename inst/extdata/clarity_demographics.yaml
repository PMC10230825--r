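# Baseline demographic distributions for the cladribine-trial-like cohort,
# transcribed (rounded) from the published trial baseline table; editable.
age: {mean: 38.0, sd: 10.0, min: 18, max: 65}
sexFemale: 0.68
weight: {mean: 70.0, sd: 14.0, min: 40, max: 120}
race: {white: 0.97, other: 0.03}
ebvRateScale: 1.0
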