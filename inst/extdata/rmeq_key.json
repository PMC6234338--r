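{
  "scale": "reduced morningness-eveningness questionnaire (5 items)",
  "items": [
    {"item": 1, "text": "preferred getting-up time", "min": 1, "max": 5},
    {"item": 2, "text": "tiredness during first half hour after waking", "min": 1, "max": 4},
    {"item": 3, "text": "time of evening tiredness / need for sleep", "min": 1, "max": 5},
    {"item": 4, "text": "time of day of feeling-best peak", "min": 1, "max": 5},
    {"item": 5, "text": "self-assessed morning/evening type", "min": 0, "max": 6}
  ],
  "classes": [
    {"label": "definitely evening", "lo": 4, "hi": 7},
    {"label": "moderately evening", "lo": 8, "hi": 11},
    {"label": "neither", "lo": 12, "hi": 17},
    {"label": "moderately morning", "lo": 18, "hi": 21},
    {"label": "definitely morning", "lo": 22, "hi": 25}
  ]
}
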