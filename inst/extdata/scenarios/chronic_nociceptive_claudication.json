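{
  "scenario_id": "chronic_nociceptive_claudication",
  "title": "Chronic nociceptive pain with symptoms of neurogenic claudication",
  "narrative": "A 71-year-old retired farmer with longstanding mechanical low back pain now reports heavy, aching legs when walking more than a block, relieved within minutes of sitting. A monitored walking test provokes the leg symptoms and flexion eases them. Findings reconstructed to match the printed condition label.",
  "findings": [
    { "item": "pain_low_back", "response": "present" },
    { "item": "pain_duration_chronic", "response": "present" },
    { "item": "pain_aggravated_movement", "response": "present" },
    { "item": "pain_relieved_rest", "response": "present" },
    { "item": "radiating_leg_pain", "response": "present" },
    { "item": "leg_symptoms_walking", "response": "present" },
    { "item": "symptoms_relieved_sitting", "response": "present" },
    { "item": "lumbar_provocation", "response": "present" },
    { "item": "extension_relief_walking", "response": "present" },
    { "item": "treadmill_provocation", "response": "present" }
  ],
  "expected_top_dx": ["dx_neurogenic_claudication", "dx_nociceptive"],
  "expected_suppressed": ["dx_piriformis"]
}
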