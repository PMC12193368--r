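# Control-like cohort: bacteria expressing a neutral dsRNA (dsEGFP analogue).
# Duration/longevity spreads are SE * sqrt(n) reconstructions from published
# cohort means; death probabilities are conditional on entering the stage.
label: dsEGFP-like
'n': 40
p_female: 0.529
stages:
  egg:   {mean: 4.3, sd: 0.63, death_prob: 0.000}
  nymph: {mean: 7.4, sd: 1.85, death_prob: 0.050}
  pupa:  {mean: 5.4, sd: 0.58, death_prob: 0.105}
apop: {mean: 2.1, sd: 0.85}
adult_longevity:
  female: {mean: 48.4, sd: 19.8}
  male:   {mean: 37.3, sd: 19.6}
# daily eggs: linear ramp over ramp_days up to peak, then exponential decay
fecundity_curve: {peak: 8.5, ramp_days: 3, decay_rate: 0.030}
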