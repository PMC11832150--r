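# Four-state late-career work-state model: states, allowed transitions
# ("from->to" state codes), covariates, and age-grid settings.
states:
- full-time
- part-time
- not in work
- death
absorbing:
- death
working:
- full-time
- part-time
transitions:
- 1->2
- 1->3
- 2->1
- 2->3
- 3->1
- 3->2
- 1->4
- 2->4
- 3->4
covariates:
- strain
- sex
age_band_width: 1
age_max: 110
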