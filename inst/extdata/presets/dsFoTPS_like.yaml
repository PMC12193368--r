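# Knockdown-like cohort: bacteria expressing dsRNA against trehalose-6-
# phosphate synthase (dsFoTPS analogue). Elevated nymph mortality, shortened
# adult life and reduced daily fecundity relative to the control preset.
label: dsFoTPS-like
'n': 40
p_female: 0.538
stages:
  egg:   {mean: 4.1, sd: 0.61, death_prob: 0.075}
  nymph: {mean: 7.3, sd: 1.06, death_prob: 0.243}
  pupa:  {mean: 5.2, sd: 1.02, death_prob: 0.071}
apop: {mean: 1.9, sd: 1.12}
adult_longevity:
  female: {mean: 26.2, sd: 9.7}
  male:   {mean: 22.9, sd: 9.0}
fecundity_curve: {peak: 4.0, ramp_days: 3, decay_rate: 0.060}
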