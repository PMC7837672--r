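{
  "task_id": "mdd",
  "version": "1.0",
  "steps": [
    {
      "step_id": "intro",
      "kind": "instruction",
      "text": "You will choose between a smaller reward now and a larger reward later. There are no right answers."
    },
    {
      "step_id": "now_or_later_money",
      "kind": "active_task",
      "engine": "dd",
      "config": {
        "n_choices": 5,
        "larger_amount": 10,
        "delays": [30, 180],
        "variant": "money",
        "start_offer": 5,
        "initial_step": 2.5,
        "preset_name": "mobile"
      }
    },
    {
      "step_id": "now_or_later_time",
      "kind": "active_task",
      "engine": "dd",
      "config": {
        "n_choices": 5,
        "larger_amount": 10,
        "delays": [180, 365],
        "variant": "time",
        "start_offer": 5,
        "initial_step": 2.5,
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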