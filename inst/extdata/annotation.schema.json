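{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rxnsketch reaction-scheme annotation",
  "type": "object",
  "required": ["canvas", "pattern", "components", "steps"],
  "properties": {
    "image_path": {"type": ["string", "null"]},
    "canvas": {
      "type": "object",
      "required": ["width", "height"],
      "properties": {
        "width": {"type": "number", "exclusiveMinimum": 0},
        "height": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "pattern": {"enum": ["single_line", "multiple_line", "branch", "cycle"]},
    "seed": {"type": "array", "items": {"type": "integer"}},
    "components": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "role", "bbox"],
        "properties": {
          "id": {"type": "string"},
          "role": {"enum": ["reactant", "condition", "product"]},
          "bbox": {"type": "array", "items": {"type": "number"}, "minItems": 4, "maxItems": 4},
          "smiles": {"type": "string"},
          "items": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["text", "role"],
              "properties": {
                "text": {"type": "string", "minLength": 1},
                "role": {"enum": ["agent", "solvent", "temperature", "time", "yield", "other"]},
                "bbox": {"type": "array", "items": {"type": "number"}, "minItems": 4, "maxItems": 4}
              }
            }
          }
        }
      }
    },
    "steps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["reactant_ids", "product_ids", "arrow"],
        "properties": {
          "reactant_ids": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "condition_ids": {"type": "array", "items": {"type": "string"}},
          "product_ids": {"type": "array", "items": {"type": "string"}, "minItems": 1},
          "arrow": {
            "type": "object",
            "required": ["start", "end", "kind"],
            "properties": {
              "start": {"type": "array", "minItems": 2, "maxItems": 2},
              "end": {"type": "array", "minItems": 2, "maxItems": 2},
              "kind": {"enum": ["straight", "curved", "bidirectional"]},
              "crossed_out": {"type": "boolean"},
              "control": {"type": ["array", "null"]}
            }
          },
          "reaction_smiles": {"type": "string"},
          "source_smiles": {"type": ["string", "null"]}
        }
      }
    }
  }
}
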