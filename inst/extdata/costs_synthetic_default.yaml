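# SYNTHETIC cost schedule -- NOT actual hospital prices.
#
# The study's itemised unit-cost supplement is not publicly available. This
# file provides a plausible, fully itemised Chinese tertiary-hospital fee
# schedule (2021 CNY) assembled from the surveillance regimen described in
# the study design: semi-annual physician visit + neck ultrasound + thyroid
# function/blood tests + laryngoscopy, with chest CT and contrast-enhanced
# neck CT once a year while the tumor is in situ. Each item carries a
# plausibility range used by generate_cost_schedule(); `value` is the
# packaged default. calibrate_costs() rescales the `surgical` and
# `surveillance` item groups so base-case lifetime totals match stated
# targets.
currency: CNY
price_year: 2021
label: synthetic_default

items:
  outpatient_visit:       {value: 12,    range: [7, 30]}
  neck_ultrasound:        {value: 150,   range: [100, 220]}
  thyroid_function_labs:  {value: 230,   range: [150, 320]}
  laryngoscopy:           {value: 180,   range: [120, 260]}
  chest_ct:               {value: 350,   range: [250, 500]}
  neck_ct_enhanced:       {value: 480,   range: [350, 700]}
  thyroxine_year:         {value: 960,   range: [600, 1400]}
  ht_surgery:             {value: 16000, range: [12000, 22000]}
  tt_surgery:             {value: 23000, range: [18000, 30000]}
  lateral_lnd:            {value: 20000, range: [15000, 26000]}
  redo_lnd:               {value: 22000, range: [17000, 29000]}
  perm_comp_mgmt:         {value: 6000,  range: [3000, 10000]}
  temp_comp_mgmt:         {value: 2500,  range: [1200, 4000]}

# Composite keys referenced by the strategy files; quantities are per year
# (cycle costs) or per event (entry costs). Composites may reference other
# composites defined earlier.
composites:
  # in-situ surveillance: full regimen twice a year + annual chest & neck CT
  as_surveillance_year:   {outpatient_visit: 2, neck_ultrasound: 2, thyroid_function_labs: 2, laryngoscopy: 2, chest_ct: 1, neck_ct_enhanced: 1}
  # post-resection follow-up: de-escalated semi-annual regimen
  postop_followup_year:   {outpatient_visit: 2, neck_ultrasound: 2, thyroid_function_labs: 2}
  postht_perm_year:       {postop_followup_year: 1, thyroxine_year: 1}
  posttt_year:            {postop_followup_year: 1, thyroxine_year: 1}
  postlnd_year:           {postop_followup_year: 1, thyroxine_year: 1}
  ht_with_perm_comp:      {ht_surgery: 1, perm_comp_mgmt: 1}
  ht_with_temp_comp:      {ht_surgery: 1, temp_comp_mgmt: 1}
  tt_with_perm_comp:      {tt_surgery: 1, perm_comp_mgmt: 1}
  lateral_lnd_with_comp:  {lateral_lnd: 1, perm_comp_mgmt: 1}
  redo_lnd_with_comp:     {redo_lnd: 1, perm_comp_mgmt: 1}

# Item groups carrying the two calibration scale factors.
groups:
  surgical:     [ht_surgery, tt_surgery, lateral_lnd, redo_lnd, perm_comp_mgmt, temp_comp_mgmt]
  surveillance: [outpatient_visit, neck_ultrasound, thyroid_function_labs, laryngoscopy, chest_ct, neck_ct_enhanced, thyroxine_year]
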