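{
  "task_id": "mbart",
  "version": "1.0",
  "steps": [
    {
      "step_id": "intro",
      "kind": "instruction",
      "text": "Pump each balloon to earn money. If it pops you lose the balloon's earnings. Tap Collect to bank them."
    },
    {
      "step_id": "balloon_game",
      "kind": "active_task",
      "engine": "bart",
      "config": {
        "n_balloons": 15,
        "threshold_max": 12,
        "reward_per_pump": 0.05,
        "preset_name": "mobile"
      }
    },
    {
      "step_id": "thanks",
      "kind": "instruction",
      "text": "Thank you! Your earnings have been recorded."
    }
  ]
}
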