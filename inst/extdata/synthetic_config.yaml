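# Synthetic fixture configuration (generated by bedflow::gen_config(),
# archetype "baseline_shortage", seed 2015). All lookup tables and the
# travelers/length-of-stay parameters are synthetic placeholders, not
# estimates from any real facility.
parameters:
  growth_proportion: 0.014
  patient_to_population_ratio: 0.129
  optimal_occupancy: 0.84999999999999998
  days_per_year: 365.0
  travelers_to_specialists_ratio: 60.0
  base_length_of_stay: 3.5
initial_stocks:
  population: 1557600.0
  number_of_bed: 3560.0
  number_of_specialist_physicians: 690.0
  capacity_of_home_care_services: 76650.0
lookups:
  F1:
    points:
    - - 0.0
      - 0.0
    - - 0.5
      - 0.00191222378346138
    - - 0.69999999999999996
      - 0.00956111891730689
    - - 0.84999999999999998
      - 0.03824447566922754
    - - 1.0
      - 0.07648895133845508
  F2:
    points:
    - - 0.05
      - 0.22746151682874186
    - - 0.12
      - 0.18610487740533424
    - - 0.20000000000000001
      - 0.14474823798192665
    - - 0.29999999999999999
      - 0.08271327884681522
    - - 0.5
      - 0.03101747956755571
  F3:
    points:
    - - 0.005
      - 0.02939583965507336
    - - 0.01
      - 0.00489930660917889
    - - 0.0125
      - 0.00195972264367156
    - - 0.015
      - 0.00058791679310147
    - - 0.02
      - 0.00019597226436716
    - - 0.03
      - 9.79861321835778787e-05
  F4:
    points:
    - - 0.0
      - 1.0
    - - 0.05
      - 0.98093713515345005
    - - 0.10000000000000001
      - 0.94281140546035014
    - - 0.25
      - 0.82843421638105064
    - - 0.5
      - 0.67593129760865134
    - - 0.80000000000000004
      - 0.57108554095262676
scenarios:
  S1:
    patient_ratio_ramp: 0.0
    los_ramp: 0.0
    travelers_ratio_ramp: 0.0
  S2:
    patient_ratio_ramp: 0.002
    los_ramp: 0.05
    travelers_ratio_ramp: 0.0
  S3:
    growth_proportion_after: 0.007
    patient_ratio_ramp: 0.002
    los_ramp: 0.05
    travelers_ratio_ramp: 0.0
  S4:
    patient_ratio_ramp: 0.002
    los_ramp: 0.05
    travelers_ratio_ramp: -1.5
policies:
  start_year: 2020.0
simulation:
  start_time: 2015.0
  stop_time: 2035.0
  dt: 0.08333333333333333
  saveper: 0.08333333333333333
synthesis:
  seed: 2015
  noise_sd: 0.05
  archetype: baseline_shortage
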