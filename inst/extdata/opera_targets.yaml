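# Calibration targets for the ocrelizumab-trial-like cohorts: the
# interferon beta-1a comparator arm's annualized relapse rate at 96 weeks.
# The selection distribution over relapse-count categories is derived from a
# negative-binomial law at this rate (dispersion nb_size).
opera1: {arr_ifnb1a: 0.352, arr_ocrelizumab: 0.195, arr_tol: 0.06}
opera2: {arr_ifnb1a: 0.346, arr_ocrelizumab: 0.191, arr_tol: 0.06}
pooled: {arr_ifnb1a: 0.349, arr_ocrelizumab: 0.193, relative_reduction: 45.7}
nb_size: 1.5
tolerance: 0.08
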