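{
  "version": "ahei2010-uk-standin-1",
  "components": [
    {"name": "vegetables", "direction": "positive", "metric": "servings/day", "zero_score_intake": 0, "full_score_intake": 5},
    {"name": "fruit", "direction": "positive", "metric": "servings/day", "zero_score_intake": 0, "full_score_intake": 4},
    {"name": "whole_grains", "direction": "positive", "metric": "g/day", "zero_score_intake": 0, "full_score_intake": 90},
    {"name": "dairy", "direction": "positive", "metric": "servings/day", "zero_score_intake": 0, "full_score_intake": 3},
    {"name": "nuts_legumes", "direction": "positive", "metric": "servings/day", "zero_score_intake": 0, "full_score_intake": 1},
    {"name": "healthy_fats", "direction": "positive", "metric": "%energy", "zero_score_intake": 2, "full_score_intake": 10},
    {"name": "oily_fish", "direction": "positive", "metric": "portions/week", "zero_score_intake": 0, "full_score_intake": 1},
    {"name": "free_sugars", "direction": "negative", "metric": "%energy", "zero_score_intake": 20, "full_score_intake": 5},
    {"name": "red_processed_meat", "direction": "negative", "metric": "servings/day", "zero_score_intake": 1.5, "full_score_intake": 0},
    {"name": "salt", "direction": "negative", "metric": "g/day", "zero_score_intake": 12, "full_score_intake": 6},
    {"name": "alcohol", "direction": "negative", "metric": "drinks/day", "zero_score_intake": 3.5, "full_score_intake": 0.5}
  ]
}
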