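{
  "scenario_id": "acute_nociceptive",
  "title": "Acute nociceptive pain",
  "narrative": "A 38-year-old warehouse worker strained their low back lifting a pallet five days ago. Pain is localised to the lumbar region, clearly worse with bending and lifting and better with rest, and is already easing day by day. No leg symptoms. Regional examination reproduces the pain on lumbar movement. Findings reconstructed to match the printed condition label; the scripted findings are the minimal set consistent with it.",
  "findings": [
    { "item": "pain_low_back", "response": "present" },
    { "item": "recent_onset_injury", "response": "present" },
    { "item": "pain_aggravated_movement", "response": "present" },
    { "item": "pain_relieved_rest", "response": "present" },
    { "item": "resolving_normal_healing", "response": "present" },
    { "item": "pain_duration_chronic", "response": "absent" },
    { "item": "lumbar_provocation", "response": "present" }
  ],
  "expected_top_dx": ["dx_nociceptive"],
  "expected_suppressed": []
}
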