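# Model input parameters -- "table1_verbatim" scenario.
#
# Decade-band progression values are stored exactly as printed in the source
# inputs table and used as ANNUAL per-cycle probabilities. Note the unit
# conflict with the text's own conversion (a 10-year cumulative 3.7% becomes
# 0.38%/year); see scenario "text_canonical" for the converted variant.
# Beta distributions are parameterised by method of moments from mean/sd.
meta:
  name: table1_verbatim
  decade_band_unit: annual_verbatim

probabilities:
  p_perm_comp_ht:     {point: 0.015,  dist: beta, mean: 0.016, sd: 0.0008, dsa: [0.014, 0.017]}
  p_temp_comp_ht:     {point: 0.015,  dist: beta, mean: 0.016, sd: 0.0008, dsa: [0.014, 0.017]}
  p_recur_ht:         {point: 0.004,  dist: beta, mean: 0.004, sd: 0.0002, dsa: [0.0036, 0.0044]}
  p_recur_tt:         {point: 0.008,  dist: beta, mean: 0.008, sd: 0.0005, dsa: [0.007, 0.009]}
  p_stable_after_ht:  {point: 0.684,  dist: beta, mean: 0.684, sd: 0.035,  dsa: [0.616, 0.752]}
  p_unirln_tt:        {point: 0.015,  dist: beta, mean: 0.016, sd: 0.0008, dsa: [0.014, 0.017]}
  p_hypopara_tt:      {point: 0.089,  dist: beta, mean: 0.09,  sd: 0.005,  dsa: [0.080, 0.098]}
  p_birln_tt:         {point: 0.003,  dist: beta, mean: 0.003, sd: 0.0002, dsa: [0.0027, 0.0033]}
  p_death_ht:         {point: 0.002,  dist: beta, mean: 0.002, sd: 0.0001, dsa: [0.0018, 0.0022]}
  p_death_tt:         {point: 0.002,  dist: beta, mean: 0.002, sd: 0.0001, dsa: [0.0018, 0.0022]}
  p_comp_lnd:         {point: 0.32,   dist: beta, mean: 0.32,  sd: 0.16,   dsa: [0.288, 0.352]}

utilities:
  u_as_stable:            {point: 0.99,   dist: beta, mean: 0.99,   sd: 0.05,  dsa: [0.89, 1]}
  u_ht_nocomp:            {point: 0.99,   dist: beta, mean: 0.99,   sd: 0.05,  dsa: [0.89, 1]}
  u_ht_perm:              {point: 0.63,   dist: beta, mean: 0.63,   sd: 0.032, dsa: [0.57, 0.69]}
  u_ht_temp:              {point: 0.627,  dist: beta, mean: 0.627,  sd: 0.032, dsa: [0.56, 0.69]}
  u_tt_birln:             {point: 0.21,   dist: beta, mean: 0.21,   sd: 0.01,  dsa: [0.19, 0.23]}
  u_tt_hypopara:          {point: 0.778,  dist: beta, mean: 0.778,  sd: 0.039, dsa: [0.7, 0.86]}
  u_tt_unirln:            {point: 0.6729, dist: beta, mean: 0.6279, sd: 0.032, dsa: [0.57, 0.69]}
  u_redo_lnd:             {point: 0.56,   dist: beta, mean: 0.56,   sd: 0.029, dsa: [0.5, 0.62]}
  u_lnd_comp:             {point: 0.41,   dist: beta, mean: 0.41,   sd: 0.02,  dsa: [0.37, 0.45]}
  u_tt_nocomp:            {point: 0.83,   dist: beta, mean: 0.83,   sd: 0.042, dsa: [0.75, 0.91]}
  # Event/decision-node style utilities: loaded for completeness and for
  # one-way sensitivity auditing, but bound to no health state in the
  # packaged strategy graphs (the state-specific utilities above are used).
  u_active_surveillance:  {point: 0.11,   dist: beta, mean: 0.11,   sd: 0.006, dsa: [0.1, 0.12]}
  u_disease_progression:  {point: 0.54,   dist: beta, mean: 0.54,   sd: 0.028, dsa: [0.49, 0.59]}
  u_early_surgery:        {point: 0.74,   dist: beta, mean: 0.74,   sd: 0.038, dsa: [0.67, 0.81]}
  u_nodal_metastasis:     {point: 0.25,   dist: beta, mean: 0.25,   sd: 0.013, dsa: [0.23, 0.28]}
  u_primary_growth:       {point: 0.54,   dist: beta, mean: 0.54,   sd: 0.028, dsa: [0.49, 0.59]}
  u_recurrence:           {point: 0.54,   dist: beta, mean: 0.54,   sd: 0.028, dsa: [0.49, 0.59]}

age_schedules:
  growth:
    - {ages: [20, 29], p: 0.22}
    - {ages: [30, 39], p: 0.084}
    - {ages: [40, 49], p: 0.0380}
    - {ages: [50, 59], p: 0.0240}
    - {ages: [60, 69], p: 0.0003}
    - {ages: [70, 79], p: 0.0006}
  nodal:
    - {ages: [20, 29], p: 0.165}
    - {ages: [30, 39], p: 0.061}
    - {ages: [40, 49], p: 0.0380}
    - {ages: [50, 59], p: 0.0240}
    - {ages: [60, 69], p: 0.0068}
    - {ages: [70, 79], p: 0.0036}

discount: 0.03
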