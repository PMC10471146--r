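# Early surgery (ES) strategy graph.
#
# The cohort undergoes upfront hemithyroidectomy + isthmectomy + unilateral
# central neck dissection at model start: the initial occupancy is the HT
# surgical-outcome split (no complication / permanent / temporary /
# operative death), with the HT entry cost charged at cycle 0. Follow-on
# surgery mirrors the AS graph: a recurrence in the remaining lobe goes to
# completion TT when confined, otherwise to lateral LND; post-TT recurrence
# goes to redo LND.
name: ES

states:
  - {name: PostHT_NoComp,   utility: u_ht_nocomp,   cycle_cost: postop_followup_year, entry_cost: ht_surgery}
  - {name: PostHT_Temp,     utility: u_ht_temp,     cycle_cost: postop_followup_year, entry_cost: ht_with_temp_comp, temporary: true}
  - {name: PostHT_Perm,     utility: u_ht_perm,     cycle_cost: postht_perm_year,     entry_cost: ht_with_perm_comp, permanent: true}
  - {name: PostTT_NoComp,   utility: u_tt_nocomp,   cycle_cost: posttt_year,          entry_cost: tt_surgery}
  - {name: PostTT_Hypopara, utility: u_tt_hypopara, cycle_cost: posttt_year,          entry_cost: tt_with_perm_comp, permanent: true}
  - {name: PostTT_UniRLN,   utility: u_tt_unirln,   cycle_cost: posttt_year,          entry_cost: tt_with_perm_comp, permanent: true}
  - {name: PostTT_BiRLN,    utility: u_tt_birln,    cycle_cost: posttt_year,          entry_cost: tt_with_perm_comp, permanent: true}
  - {name: PostLND,         utility: u_redo_lnd,    cycle_cost: postlnd_year}
  - {name: LNDComp,         utility: u_lnd_comp,    cycle_cost: postlnd_year,         permanent: true}
  - {name: Death,           utility: 0,             absorbing: true}

# Upfront HT at cycle 0: outcome split over the same Table-driven
# surgical-outcome probabilities used for a growth-triggered HT.
initial:
  PostHT_NoComp: {one_minus_sum: [p_death_ht, p_perm_comp_ht, p_temp_comp_ht]}
  PostHT_Perm:   {param: p_perm_comp_ht}
  PostHT_Temp:   {param: p_temp_comp_ht}
  Death:         {param: p_death_ht}

transitions:
  # recurrence in the remaining lobe: confined -> completion TT; else lateral LND
  - {from: PostHT_NoComp, to: Death,           factors: [{param: p_recur_ht}, {param: p_stable_after_ht}, {param: p_death_tt}]}
  - {from: PostHT_NoComp, to: PostTT_Hypopara, factors: [{param: p_recur_ht}, {param: p_stable_after_ht}, {param: p_hypopara_tt}]}
  - {from: PostHT_NoComp, to: PostTT_UniRLN,   factors: [{param: p_recur_ht}, {param: p_stable_after_ht}, {param: p_unirln_tt}]}
  - {from: PostHT_NoComp, to: PostTT_BiRLN,    factors: [{param: p_recur_ht}, {param: p_stable_after_ht}, {param: p_birln_tt}]}
  - {from: PostHT_NoComp, to: PostTT_NoComp,   factors: [{param: p_recur_ht}, {param: p_stable_after_ht}, {one_minus_sum: [p_death_tt, p_hypopara_tt, p_unirln_tt, p_birln_tt]}]}
  - {from: PostHT_NoComp, to: LNDComp,  factors: [{param: p_recur_ht}, {complement: p_stable_after_ht}, {param: p_comp_lnd}],      entry_cost: lateral_lnd_with_comp}
  - {from: PostHT_NoComp, to: PostLND,  factors: [{param: p_recur_ht}, {complement: p_stable_after_ht}, {complement: p_comp_lnd}], entry_cost: lateral_lnd}
  - {from: PostHT_NoComp, to: PostHT_NoComp, residual: true}

  # temporary complication resolves after one cycle (no re-charged surgery)
  - {from: PostHT_Temp, to: PostHT_NoComp, residual: true, charge_entry: false}
  - {from: PostHT_Perm, to: PostHT_Perm, residual: true}

  # post-TT recurrence -> redo (lateral) lymph node dissection
  - {from: PostTT_NoComp, to: LNDComp,  factors: [{param: p_recur_tt}, {param: p_comp_lnd}],      entry_cost: redo_lnd_with_comp}
  - {from: PostTT_NoComp, to: PostLND,  factors: [{param: p_recur_tt}, {complement: p_comp_lnd}], entry_cost: redo_lnd}
  - {from: PostTT_NoComp, to: PostTT_NoComp, residual: true}
  - {from: PostTT_Hypopara, to: PostTT_Hypopara, residual: true}
  - {from: PostTT_UniRLN, to: PostTT_UniRLN, residual: true}
  - {from: PostTT_BiRLN, to: PostTT_BiRLN, residual: true}

  - {from: PostLND, to: PostLND, residual: true}
  - {from: LNDComp, to: LNDComp, residual: true}
  - {from: Death, to: Death, residual: true}
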