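{
  "language": "en",
  "matching": {"mode": "word_boundary", "case_sensitive": false},
  "entries": [
    {
      "factor_id": "meal_dependent",
      "provenance": "paper",
      "fields": ["instructions"],
      "phrases": ["meal", "food", "eat", "breakfast", "lunch", "dinner"]
    },
    {
      "factor_id": "once_weekly",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["once weekly", "once a week", "weekly", "every week", "same day each week"]
    },
    {
      "factor_id": "every_two_days_or_less",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["every two days", "every other day", "every second day", "every three days", "alternate days", "once monthly", "every month"]
    },
    {
      "factor_id": "fixed_dosing_interval",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["every 6 hours", "every 8 hours", "every 12 hours", "exact interval", "fixed interval", "evenly spaced"]
    },
    {
      "factor_id": "occasional_episodic",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["short course", "episodic", "limited time", "until the pack is finished", "for one week only"]
    },
    {
      "factor_id": "prn_medication",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["as needed", "if necessary", "if needed", "when required", "as required"]
    },
    {
      "factor_id": "crushing_tablets",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["crush", "crushed", "crushing"]
    },
    {
      "factor_id": "disintegrating_forms",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["dissolve", "dissolved", "disperse", "dispersed", "effervescent"]
    },
    {
      "factor_id": "fixed_times_of_day",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["bedtime", "exact time", "certain time of day", "at 8 am", "at 8 pm"]
    },
    {
      "factor_id": "advised_liquid_intake",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["plenty of water", "glass of water", "with milk", "with juice", "upright position"]
    },
    {
      "factor_id": "opening_capsules",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["open the capsule", "open the capsules", "sprinkle the contents", "capsule may be opened"]
    },
    {
      "factor_id": "increasing_doses",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["increase the dose", "increasing dose", "titrate up", "up-titration", "dose increase"]
    },
    {
      "factor_id": "decreasing_doses",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["reduce the dose", "decreasing dose", "taper", "tapering", "down-titration", "dose reduction"]
    },
    {
      "factor_id": "complex_measurements",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["blood glucose", "blood sugar", "blood coagulation", "INR", "self-measurement"]
    }
  ]
}
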