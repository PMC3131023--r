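# Delayed-logistic parameter presets per degraded area type.
# Units: initial_level_mg and recovery_level_mg in mg MIB, delay_years in
# years, increase_rate_per_year in 1/years. `unverified` lists parameters
# that field data could not confirm (the ash-heap increase rate is a
# theoretical value).
forest_soil_planted:
  initial_level_mg: 40
  delay_years: 0
  increase_rate_per_year: 0.18
  recovery_level_mg: 290
  unverified: [initial, delay, rate]
post_agri_natural:
  initial_level_mg: 40
  delay_years: 0
  increase_rate_per_year: 0.18
  recovery_level_mg: 250
  unverified: []
post_agri_planted:
  initial_level_mg: 40
  delay_years: 0
  increase_rate_per_year: 0.5
  recovery_level_mg: 250
  unverified: []
ash_heap:
  initial_level_mg: 40
  delay_years: 10
  increase_rate_per_year: 0.28
  recovery_level_mg: 210
  unverified: [delay, rate, recovery]
mining_heap:
  initial_level_mg: 40
  delay_years: 10
  increase_rate_per_year: 0.6
  recovery_level_mg: 210
  unverified: []
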