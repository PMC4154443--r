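[
  {
    "rule_id": "rod_ribbon_arboreal",
    "focal_class": "AII",
    "partner_group": "RodBC",
    "focal_compartment": "arboreal",
    "kind": "ribbon_input",
    "mode": "required_on_encounter",
    "direction": "focal_post"
  },
  {
    "rule_id": "rod_no_output",
    "focal_class": "AII",
    "partner_group": "RodBC",
    "focal_compartment": "any",
    "kind": "conventional_synapse",
    "mode": "forbidden",
    "direction": "focal_pre"
  },
  {
    "rule_id": "rod_no_coupling",
    "focal_class": "AII",
    "partner_group": "RodBC",
    "focal_compartment": "any",
    "kind": "gap_junction",
    "mode": "forbidden",
    "direction": "symmetric"
  },
  {
    "rule_id": "cbb_coupling_waist",
    "focal_class": "AII",
    "partner_group": "CBbAll",
    "focal_compartment": "waist",
    "kind": "gap_junction",
    "mode": "required_on_encounter",
    "direction": "symmetric"
  },
  {
    "rule_id": "cbb_coupling_arboreal",
    "focal_class": "AII",
    "partner_group": "CBbAll",
    "focal_compartment": "arboreal",
    "kind": "gap_junction",
    "mode": "required_on_encounter",
    "direction": "symmetric"
  },
  {
    "rule_id": "cbb_no_coupling_off",
    "focal_class": "AII",
    "partner_group": "CBbAll",
    "focal_compartment": "lobule",
    "kind": "gap_junction",
    "mode": "forbidden",
    "direction": "symmetric"
  },
  {
    "rule_id": "cbb_no_ribbon",
    "focal_class": "AII",
    "partner_group": "CBb",
    "focal_compartment": "any",
    "kind": "ribbon_input",
    "mode": "forbidden",
    "direction": "focal_post"
  },
  {
    "rule_id": "cbb7_ribbon",
    "focal_class": "AII",
    "partner_group": "CBb7",
    "focal_compartment": "arboreal",
    "kind": "ribbon_input",
    "mode": "permitted",
    "direction": "focal_post"
  },
  {
    "rule_id": "cbb7_ribbon_waist",
    "focal_class": "AII",
    "partner_group": "CBb7",
    "focal_compartment": "waist",
    "kind": "ribbon_input",
    "mode": "permitted",
    "direction": "focal_post"
  },
  {
    "rule_id": "cba_input",
    "focal_class": "AII",
    "partner_group": "CBa",
    "focal_compartment": "lobule",
    "kind": "ribbon_input",
    "mode": "permitted",
    "direction": "focal_post"
  },
  {
    "rule_id": "cba_output",
    "focal_class": "AII",
    "partner_group": "CBa",
    "focal_compartment": "lobule",
    "kind": "conventional_synapse",
    "mode": "permitted",
    "direction": "focal_pre"
  },
  {
    "rule_id": "cba_no_coupling",
    "focal_class": "AII",
    "partner_group": "CBa",
    "focal_compartment": "any",
    "kind": "gap_junction",
    "mode": "forbidden",
    "direction": "symmetric"
  },
  {
    "rule_id": "aii_coupling_arboreal",
    "focal_class": "AII",
    "partner_group": "AII",
    "focal_compartment": "arboreal",
    "kind": "gap_junction",
    "mode": "required_on_encounter",
    "direction": "symmetric"
  },
  {
    "rule_id": "aii_coupling_waist",
    "focal_class": "AII",
    "partner_group": "AII",
    "focal_compartment": "waist",
    "kind": "gap_junction",
    "mode": "permitted",
    "direction": "symmetric"
  },
  {
    "rule_id": "aii_no_lobule_coupling",
    "focal_class": "AII",
    "partner_group": "AII",
    "focal_compartment": "lobule",
    "kind": "gap_junction",
    "mode": "forbidden",
    "direction": "symmetric"
  },
  {
    "rule_id": "offgc_lobule_output",
    "focal_class": "AII",
    "partner_group": "OFF-alpha-GC",
    "focal_compartment": "lobule",
    "kind": "conventional_synapse",
    "mode": "required_on_encounter",
    "direction": "focal_pre"
  },
  {
    "rule_id": "gc_lobule_output",
    "focal_class": "AII",
    "partner_group": "GC",
    "focal_compartment": "lobule",
    "kind": "conventional_synapse",
    "mode": "permitted",
    "direction": "focal_pre"
  },
  {
    "rule_id": "gc_arboreal_touch_only",
    "focal_class": "AII",
    "partner_group": "GC",
    "focal_compartment": "arboreal",
    "kind": "any_specialization",
    "mode": "forbidden",
    "direction": "any"
  },
  {
    "rule_id": "ai_no_off_synapse",
    "focal_class": "AII",
    "partner_group": "AI",
    "focal_compartment": "lobule",
    "kind": "conventional_synapse",
    "mode": "forbidden",
    "direction": "any"
  },
  {
    "rule_id": "ai_adherens",
    "focal_class": "AII",
    "partner_group": "AI",
    "focal_compartment": "arboreal",
    "kind": "adherens",
    "mode": "permitted",
    "direction": "symmetric"
  },
  {
    "rule_id": "ac_input",
    "focal_class": "AII",
    "partner_group": "gammaAC",
    "focal_compartment": "any",
    "kind": "conventional_synapse",
    "mode": "permitted",
    "direction": "focal_post"
  },
  {
    "rule_id": "gac_output",
    "focal_class": "AII",
    "partner_group": "GAC",
    "focal_compartment": "lobule",
    "kind": "conventional_synapse",
    "mode": "permitted",
    "direction": "focal_pre"
  },
  {
    "rule_id": "th1_input",
    "focal_class": "AII",
    "partner_group": "TH1",
    "focal_compartment": "neck",
    "kind": "conventional_synapse",
    "mode": "permitted",
    "direction": "focal_post"
  },
  {
    "rule_id": "output_lobule_only_n",
    "focal_class": "AII",
    "partner_group": "any",
    "focal_compartment": "neck",
    "kind": "conventional_synapse",
    "mode": "forbidden",
    "direction": "focal_pre"
  },
  {
    "rule_id": "output_lobule_only_w",
    "focal_class": "AII",
    "partner_group": "any",
    "focal_compartment": "waist",
    "kind": "conventional_synapse",
    "mode": "forbidden",
    "direction": "focal_pre"
  },
  {
    "rule_id": "output_lobule_only_a",
    "focal_class": "AII",
    "partner_group": "any",
    "focal_compartment": "arboreal",
    "kind": "conventional_synapse",
    "mode": "forbidden",
    "direction": "focal_pre"
  }
]
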