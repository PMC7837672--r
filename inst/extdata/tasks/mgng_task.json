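{
  "task_id": "mgng",
  "version": "1.0",
  "steps": [
    {
      "step_id": "intro",
      "kind": "instruction",
      "text": "Tap the screen as fast as possible when a green rectangle appears; do not tap for blue rectangles."
    },
    {
      "step_id": "square_test",
      "kind": "active_task",
      "engine": "gng",
      "config": {
        "n_trials": 75,
        "cue_validity": 0.7,
        "soa_set": [100, 200, 300, 400, 500, 750],
        "fixation_ms": 250,
        "blank_ms": 250,
        "target_window_ms": 500,
        "iti_ms": 250,
        "go_cue_orientation": "horizontal",
        "preset_name": "mobile"
      }
    },
    {
      "step_id": "thanks",
      "kind": "instruction",
      "text": "Done! Thank you."
    }
  ]
}
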