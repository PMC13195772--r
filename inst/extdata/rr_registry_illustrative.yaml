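causes:
  alcohol_use_disorders:
    icd10:
    - F10
    - X45
    - K860
    attribution: fully_attributable
    hed_stratified: no
    functions: []
  liver_cirrhosis:
    icd10:
    - K70
    - K74
    attribution: partially_attributable
    hed_stratified: no
    functions:
    - sex: male
      age_group: all
      group: current
      form: log-linear
      beta:
      - 0.018
      cov:
      - - 4.0e-06
      range: 150.0
    - sex: female
      age_group: all
      group: current
      form: log-linear
      beta:
      - 0.023
      cov:
      - - 6.0e-06
      range: 150.0
    - sex: all
      age_group: all
      group: former
      form: constant
      beta:
      - 0.27002713721306
      cov:
      - - 0.01
      range: 150.0
  ischemic_heart_disease:
    icd10:
    - I20-I25
    attribution: partially_attributable
    hed_stratified: yes
    functions:
    - sex: all
      age_group: all
      group: current_non_hed
      form: log-quadratic
      beta:
      - -0.0075
      - 8.000000000000001e-05
      cov:
      - - 4.0e-06
        - -1.5e-08
      - - -1.5e-08
        - 2.5e-10
      range: 150.0
    - sex: all
      age_group: all
      group: current_hed
      form: log-linear
      beta:
      - 0.0045
      cov:
      - - 2.5e-06
      range: 150.0
    - sex: all
      age_group: all
      group: former
      form: constant
      beta:
      - 0.113328685307003
      cov:
      - - 0.004
      range: 150.0
  motor_vehicle_injuries:
    icd10:
    - V01-V89
    attribution: partially_attributable
    hed_stratified: yes
    functions:
    - sex: all
      age_group: all
      group: current_non_hed
      form: log-linear
      beta:
      - 0.004
      cov:
      - - 2.0e-06
      range: 150.0
    - sex: all
      age_group: all
      group: current_hed
      form: log-linear
      beta:
      - 0.011
      cov:
      - - 4.0e-06
      range: 150.0
    - sex: all
      age_group: all
      group: former
      form: constant
      beta:
      - 0.0
      cov:
      - - 0.002
      range: 150.0
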