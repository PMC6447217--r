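{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "FFQ response",
  "type": "object",
  "required": ["respondent", "answers"],
  "properties": {
    "respondent": {
      "type": "object",
      "required": ["name", "sex", "age", "height", "weight"],
      "properties": {
        "name": {"type": "string", "minLength": 1},
        "sex": {"enum": ["M", "F"]},
        "age": {"type": "number", "exclusiveMinimum": 0},
        "height": {"type": "number", "exclusiveMinimum": 0,
                   "description": "metres"},
        "weight": {"type": "number", "exclusiveMinimum": 0,
                   "description": "kilograms"}
      }
    },
    "answers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["item_id", "frequency", "portion_multiplier"],
        "properties": {
          "item_id": {"type": "string"},
          "frequency": {"type": "string",
                        "description": "a frequency-dialect label"},
          "portion_multiplier": {"type": "number", "minimum": 0}
        }
      }
    },
    "activity": {
      "type": "object",
      "description": "optional 16-item Baecke questionnaire answers, 1-5 each",
      "additionalProperties": {"type": "integer", "minimum": 1, "maximum": 5}
    }
  }
}
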