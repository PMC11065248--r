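{
  "_comment": "The nine WHO interventions judged feasible for modeling. Unit costs are the printed study costs (2023 international dollars). Effect rate ratios are replaceable literature-style defaults; scenario analyses that must match the published panels configure condition deltas directly from the effect-panel fixture instead.",
  "interventions": [
    {
      "who_id": "1.4",
      "label": "Ban tobacco smoking in indoor workplaces, public places and transport",
      "domain": "Reduce tobacco use",
      "eligibility": {"type": "all"},
      "mechanism": [
        {"target": "cvd", "channel": "incidence_rr", "rr": 0.90},
        {"target": "asthma_copd", "channel": "incidence_rr", "rr": 0.95}
      ],
      "cost_model": {"basis": "per_person_year", "unit_cost": 0.20, "program_fixed": 0}
    },
    {
      "who_id": "2.11",
      "label": "Nutrition education and counseling in schools, workplaces and hospitals",
      "domain": "Reduce unhealthy diet",
      "eligibility": {"type": "all"},
      "mechanism": [
        {"target": "cvd", "channel": "incidence_rr", "rr": 0.997},
        {"target": "diabetes", "channel": "incidence_rr", "rr": 0.997}
      ],
      "cost_model": {"basis": "per_person_year", "unit_cost": 4, "program_fixed": 0}
    },
    {
      "who_id": "2.13",
      "label": "Mass media campaign on healthy diets",
      "domain": "Reduce unhealthy diet",
      "eligibility": {"type": "all"},
      "mechanism": [
        {"target": "cvd", "channel": "incidence_rr", "rr": 0.995},
        {"target": "diabetes", "channel": "incidence_rr", "rr": 0.996}
      ],
      "cost_model": {"basis": "per_person_year", "unit_cost": 0.30, "program_fixed": 0}
    },
    {
      "who_id": "3.1",
      "label": "Community-wide public education and awareness campaign for physical activity",
      "domain": "Reduce physical inactivity",
      "eligibility": {"type": "all"},
      "mechanism": [
        {"target": "cvd", "channel": "incidence_rr", "rr": 0.996},
        {"target": "diabetes", "channel": "incidence_rr", "rr": 0.995},
        {"target": "asthma_copd", "channel": "incidence_rr", "rr": 0.995},
        {"target": "colorectal_cancer", "channel": "incidence_rr", "rr": 0.99}
      ],
      "cost_model": {"basis": "per_person_year", "unit_cost": 19, "program_fixed": 0}
    },
    {
      "who_id": "3.2",
      "label": "Physical activity counseling and referral in routine primary care",
      "domain": "Reduce physical inactivity",
      "eligibility": {"type": "all"},
      "mechanism": [
        {"target": "cvd", "channel": "incidence_rr", "rr": 0.99},
        {"target": "diabetes", "channel": "incidence_rr", "rr": 0.988},
        {"target": "asthma_copd", "channel": "incidence_rr", "rr": 0.99},
        {"target": "breast_cancer", "channel": "incidence_rr", "rr": 0.99},
        {"target": "colorectal_cancer", "channel": "incidence_rr", "rr": 0.99}
      ],
      "cost_model": {"basis": "per_person_year", "unit_cost": 110, "program_fixed": 0}
    },
    {
      "who_id": "6.2",
      "label": "Mammography screening every 2 years, women 50-69, with timely treatment",
      "domain": "Manage cancer",
      "eligibility": {"type": "female_age_band", "age_lo": 50, "age_hi": 69},
      "mechanism": [
        {"target": "breast_cancer", "channel": "mortality_rr", "rr": 0.80}
      ],
      "cost_model": {"basis": "per_person_year", "unit_cost": 20, "program_fixed": 0,
                     "note": "already averaged over sex and the biennial frequency"}
    },
    {
      "who_id": "6.3",
      "label": "Treatment of colorectal cancer stages I-II (surgery +/- chemo/radiotherapy)",
      "domain": "Manage cancer",
      "eligibility": {"type": "incident_case", "target": "colorectal_cancer"},
      "mechanism": [
        {"target": "colorectal_cancer", "channel": "mortality_rr", "rr": 0.60}
      ],
      "cost_model": {"basis": "per_incident_case", "unit_cost": 14736, "program_fixed": 0}
    },
    {
      "who_id": "6.4",
      "label": "Treatment of breast cancer stages I-II (surgery +/- systemic therapy)",
      "domain": "Manage cancer",
      "eligibility": {"type": "incident_case", "target": "breast_cancer"},
      "mechanism": [
        {"target": "breast_cancer", "channel": "mortality_rr", "rr": 0.60}
      ],
      "cost_model": {"basis": "per_incident_case", "unit_cost": 1423, "program_fixed": 0}
    },
    {
      "who_id": "7.3",
      "label": "Asthma treatment with low-dose inhaled beclometasone and SABA",
      "domain": "Manage chronic respiratory disease",
      "eligibility": {"type": "dx_flag", "field": "dx_asthma_copd"},
      "mechanism": [
        {"target": "asthma_copd", "channel": "incidence_rr", "rr": 0.95},
        {"target": "asthma_copd", "channel": "mortality_rr", "rr": 0.75}
      ],
      "cost_model": {"basis": "per_eligible_person_year", "unit_cost": 24,
                     "program_fixed": 0, "eligible_fraction": 0.098}
    }
  ]
}
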