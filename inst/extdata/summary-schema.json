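{
  "title": "ltra example summary",
  "description": "Required fields of the JSON summary written by run_example(), with their JSON types.",
  "required": {
    "fixture": "string",
    "horizon": "number",
    "total_baseline_cost": "number",
    "total_intervention_cost": "number",
    "total_payment_one_year": "number",
    "total_payment_long_term": "number",
    "surplus_long_term": "number",
    "surplus_one_year": "number",
    "npv_long_term": "number",
    "npv_one_year": "number"
  }
}
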