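{
  "scenario_id": "multifactorial",
  "title": "Complex multifactorial presentation",
  "narrative": "A 68-year-old with chronic low back pain showing evidence for all three pain-mechanism categories: mechanical aggravation, nerve-root sensory changes with leg symptoms provoked by walking and relieved by sitting, and widespread pain with unrefreshing sleep, distress and diffuse tenderness. Buttock pain and sciatic notch tenderness are present, so the piriformis-syndrome rule triggers, but the historical and examination evidence for neurogenic claudication is stronger and the model rejects piriformis syndrome in its favour. Findings reconstructed; the scripted set is the minimal one consistent with the demonstrated behaviour.",
  "findings": [
    { "item": "pain_low_back", "response": "present" },
    { "item": "pain_duration_chronic", "response": "present" },
    { "item": "pain_aggravated_movement", "response": "present" },
    { "item": "radiating_leg_pain", "response": "present" },
    { "item": "sensory_changes_nerve_root", "response": "present" },
    { "item": "leg_symptoms_walking", "response": "present" },
    { "item": "buttock_pain", "response": "present" },
    { "item": "pain_widespread", "response": "present" },
    { "item": "sleep_disturbance", "response": "present" },
    { "item": "psychosocial_stressors", "response": "present" },
    { "item": "symptoms_relieved_sitting", "response": "present" },
    { "item": "pain_unpredictable", "response": "present" },
    { "item": "lumbar_provocation", "response": "present" },
    { "item": "extension_relief_walking", "response": "present" },
    { "item": "treadmill_provocation", "response": "present" },
    { "item": "widespread_tenderness", "response": "present" },
    { "item": "sciatic_notch_tenderness", "response": "present" }
  ],
  "expected_top_dx": ["dx_neurogenic_claudication", "dx_nociplastic"],
  "expected_suppressed": ["dx_piriformis"]
}
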