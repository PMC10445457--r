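# Buchwald-Hartwig amination optimization domain:
# catalyst and base as categorical variables, temperature and residence
# time as continuous variables.
continuous:
  temperature_C: [50, 100]
  residence_time_min: [5, 60]
categorical:
  catalyst:
    - tBuBrettPhos Pd G3
    - tBuXPhos Pd G3
  base:
    - DBU
    - BTMG
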