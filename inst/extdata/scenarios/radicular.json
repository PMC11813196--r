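{
  "scenario_id": "radicular",
  "title": "Radicular pain",
  "narrative": "A 42-year-old landscaper with two weeks of sharp right leg pain shooting below the knee, worse with coughing, following a dermatomal band, with tingling and numbness in the foot. Straight leg raise reproduces the leg pain on the symptomatic side and crossed straight leg raise is positive. Findings reconstructed to match the printed condition label.",
  "findings": [
    { "item": "pain_low_back", "response": "present" },
    { "item": "radiating_leg_pain", "response": "present" },
    { "item": "sensory_changes_nerve_root", "response": "present" },
    { "item": "dermatomal_distribution", "response": "present" },
    { "item": "pain_below_knee", "response": "present" },
    { "item": "increased_pain_cough_sneeze", "response": "present" },
    { "item": "numbness_leg", "response": "present" },
    { "item": "slr_positive", "response": "present" },
    { "item": "crossed_slr", "response": "present" }
  ],
  "expected_top_dx": ["dx_radicular"],
  "expected_suppressed": []
}
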