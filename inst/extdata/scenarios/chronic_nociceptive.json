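{
  "scenario_id": "chronic_nociceptive",
  "title": "Chronic nociceptive pain",
  "narrative": "A 55-year-old office manager with eight months of recurrent mechanical low back pain. Pain flares with loading and eases with rest; there are no leg symptoms and no features of widespread pain. Lumbar movement reproduces the familiar pain. Findings reconstructed to match the printed condition label.",
  "findings": [
    { "item": "pain_low_back", "response": "present" },
    { "item": "pain_duration_chronic", "response": "present" },
    { "item": "pain_aggravated_movement", "response": "present" },
    { "item": "pain_relieved_rest", "response": "present" },
    { "item": "lumbar_provocation", "response": "present" }
  ],
  "expected_top_dx": ["dx_nociceptive"],
  "expected_suppressed": []
}
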