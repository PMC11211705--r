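# Reference codebook: subevent codes per impact area, contributing
# factors, and policy/management responses. Keywords are matched
# case-folded on token boundaries against summary text; a residual code
# is assigned when no sibling keyword code of the same theme matched
# (e.g. unspecified vaccination status = absence of any dose keyword).
codes:
  # --- area of impact: infections and deaths ---
  - code: sub_infections
    label: Infections
    theme: area_of_impact
    topics: [infections_deaths]
    keywords: ["tested positive"]
  - code: sub_deaths
    label: Deaths
    theme: area_of_impact
    topics: [infections_deaths]
    keywords: ["passed away"]
  - code: sub_both
    label: Infections and deaths
    theme: area_of_impact
    topics: [infections_deaths]
    keywords: ["casualty toll"]
  # --- area of impact: mental health ---
  - code: mh_anxiety
    label: Anxiety
    theme: area_of_impact
    topics: [mental_health]
    keywords: [anxiety]
  - code: mh_burnout
    label: Burnout
    theme: area_of_impact
    topics: [mental_health]
    keywords: [burnout]
  - code: mh_depression
    label: Depression
    theme: area_of_impact
    topics: [mental_health]
    keywords: [depression]
  - code: mh_exhaustion
    label: Exhaustion, overwork, and fatigue
    theme: area_of_impact
    topics: [mental_health]
    keywords: [exhaustion, overwork, fatigue]
  - code: mh_sleep
    label: Sleep issues
    theme: area_of_impact
    topics: [mental_health]
    keywords: [insomnia]
  - code: mh_stress
    label: Stress
    theme: area_of_impact
    topics: [mental_health]
    keywords: [stress]
  - code: mh_suicide
    label: Suicide
    theme: area_of_impact
    topics: [mental_health]
    keywords: [suicide]
  - code: mh_trauma
    label: Trauma and traumatic stress
    theme: area_of_impact
    topics: [mental_health]
    keywords: [trauma]
  # --- area of impact: industrial action ---
  - code: ia_demonstration
    label: Demonstration, picket, or protest
    theme: area_of_impact
    topics: [industrial_action]
    keywords: [rally]
  - code: ia_walkout
    label: Sit-down or walkout
    theme: area_of_impact
    topics: [industrial_action]
    keywords: ["work stoppage"]
  - code: ia_strike
    label: Strike
    theme: area_of_impact
    topics: [industrial_action]
    keywords: ["downed tools"]
  # --- area of impact: vaccination ---
  - code: vac_first
    label: First dose
    theme: area_of_impact
    topics: [vaccination]
    keywords: ["first dose"]
  - code: vac_second
    label: Second dose or fully vaccinated
    theme: area_of_impact
    topics: [vaccination]
    keywords: ["second dose"]
  - code: vac_booster
    label: Booster dose
    theme: area_of_impact
    topics: [vaccination]
    keywords: [booster]
  - code: vac_unspecified
    label: Unspecified
    theme: area_of_impact
    topics: [vaccination]
    residual: true
  # --- area of impact: health professionals' education ---
  - code: edu_exams
    label: Exam postponement
    theme: area_of_impact
    topics: [education]
    keywords: [postponed]
  - code: edu_clinical
    label: Suspension of clinical training
    theme: area_of_impact
    topics: [education]
    keywords: ["clinical placements"]
  - code: edu_classes
    label: Suspension of in-person classes
    theme: area_of_impact
    topics: [education]
    keywords: ["classroom teaching"]
  - code: edu_celebrations
    label: Suspension of in-person celebrations
    theme: area_of_impact
    topics: [education]
    keywords: ["commencement ceremony"]
  - code: edu_visa
    label: Visa issues
    theme: area_of_impact
    topics: [education]
    keywords: [visa]
  - code: edu_other
    label: Other disruptions
    theme: area_of_impact
    topics: [education]
    keywords: [accreditation]
  # --- contributing factors (apply to every topic) ---
  - code: cf_remuneration
    label: Remuneration and compensation
    theme: contributing_factor
    keywords: [wages]
  - code: cf_ppe
    label: Lack of adequate PPE
    theme: contributing_factor
    keywords: ["protective equipment"]
  - code: cf_workload
    label: Excessive workload
    theme: contributing_factor
    keywords: [workload]
  - code: cf_staffing
    label: Staff shortages
    theme: contributing_factor
    keywords: [staffing]
  - code: cf_risk
    label: Occupational risks
    theme: contributing_factor
    keywords: [hazard]
  - code: cf_vaccine_safety
    label: Vaccine safety concerns
    theme: contributing_factor
    keywords: ["side effects"]
  # --- responses (apply to every topic) ---
  - code: rs_pay
    label: Personnel affairs and pay packages
    theme: response
    keywords: ["salary increment"]
  - code: rs_therapy
    label: Therapeutic support
    theme: response
    keywords: ["psychosocial support"]
  - code: rs_mandate
    label: Mandates
    theme: response
    keywords: [mandate]
  - code: rs_supply
    label: Supply strategies
    theme: response
    keywords: [procurement]
  - code: rs_discipline
    label: Disciplinary action
    theme: response
    keywords: [sanctions]
  - code: rs_technology
    label: Technology
    theme: response
    keywords: [telemedicine]
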