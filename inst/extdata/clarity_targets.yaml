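# Calibration targets for the cladribine-trial-like placebo arm at week 96:
# relapse-count distribution and worst lymphocytopenia-grade distribution.
relapse_distribution: {"0": 0.605, "1": 0.250, "2": 0.098, "3": 0.040, "4+": 0.007}
grade_distribution: {"0": 0.8373, "1": 0.0987, "2": 0.0640, "3": 0.0, "4": 0.0}
tolerance: 0.05
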