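{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "medcomplexity knowledge base",
  "description": "Catalogue of complexity factors, the question bank, and the measure registry. Validated at load time by validate_kb(); this schema documents the file layout.",
  "type": "object",
  "required": ["factors", "questions", "measures"],
  "properties": {
    "kb_version": {"type": "string"},
    "language": {"type": "string"},
    "factors": {
      "type": "array",
      "minItems": 61,
      "maxItems": 61,
      "items": {
        "type": "object",
        "required": ["factor_id", "label", "category", "automated", "in_tool",
                     "question_ids", "measure_ids"],
        "properties": {
          "factor_id": {"type": "string", "pattern": "^[a-z0-9_]+$"},
          "label": {"type": "string"},
          "category": {"enum": ["dosage_form", "dosage_scheme",
                                "additional_instructions", "patient",
                                "product", "process"]},
          "automated": {"type": "boolean"},
          "detection_mechanism": {"enum": ["pzn", "dosage_scheme",
                                           "schedule_lines", "keywords",
                                           "pzn_and_keywords"]},
          "device_subtypes": {"type": "array", "items": {"type": "string"}},
          "in_tool": {"type": "boolean"},
          "question_ids": {"type": "array", "items": {"type": "string"}},
          "measure_ids": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "questions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["question_id", "kind", "parts"],
        "properties": {
          "question_id": {"type": "string"},
          "kind": {"enum": ["key", "distinct", "open"]},
          "device_subtype": {"type": "string"},
          "fallback": {"type": "boolean"},
          "shared_by": {"type": "array", "items": {"type": "string"}},
          "parts": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["text", "answer_type", "predicate"],
              "properties": {
                "text": {"type": "string"},
                "answer_type": {"enum": ["yes_no", "numeric", "free_text"]},
                "predicate": {
                  "type": "object",
                  "required": ["name"],
                  "properties": {
                    "name": {"enum": ["yes_is_problem", "no_is_problem",
                                      "numeric_below", "numeric_above", "info"]},
                    "threshold": {"type": "number"}
                  }
                }
              }
            }
          }
        }
      }
    },
    "measures": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["measure_id", "type", "title"],
        "properties": {
          "measure_id": {"type": "string"},
          "type": {"enum": ["recommendation_for_action", "training_material",
                            "algorithm"]},
          "topic": {"enum": ["aid", "explain", "review"]},
          "resource_ref": {"type": "string"},
          "algorithm_ref": {"enum": ["alternative_strength", "alternative_form",
                                     "frequency_reduction",
                                     "combination_product", "prefilled_device"]},
          "title": {"type": "string"}
        }
      }
    }
  }
}
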