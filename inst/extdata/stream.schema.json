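{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/handfusion/stream.schema.json",
  "title": "Session stream line (JSON Lines: line 1 header, lines 2..N frame records)",
  "oneOf": [
    {
      "type": "object",
      "required": ["header"],
      "properties": {
        "header": {
          "type": "object",
          "required": ["patient_id", "therapist_id", "device_id", "task",
                       "calibration_ref", "schema_version"],
          "properties": {
            "patient_id": {"type": "string", "minLength": 1},
            "therapist_id": {"type": "string", "minLength": 1},
            "device_id": {"type": "string", "minLength": 1},
            "task": {
              "type": "object",
              "required": ["type", "difficulty", "duration", "repetitions",
                           "start_date"],
              "properties": {
                "type": {"type": "string"},
                "difficulty": {"type": "number"},
                "duration": {"type": "number", "exclusiveMinimum": 0},
                "repetitions": {"type": "integer", "minimum": 1},
                "start_date": {"type": "string"},
                "params_id": {"type": "string"},
                "score": {"type": "number"}
              }
            },
            "calibration_ref": {"type": "string"},
            "schema_version": {"type": "string"}
          }
        }
      }
    },
    {
      "type": "object",
      "required": ["t", "models"],
      "properties": {
        "t": {"type": "number", "description": "timestamp [ms]"},
        "models": {
          "type": "object",
          "minProperties": 1,
          "propertyNames": {"enum": ["vertical", "horizontal", "fused", "truth"]},
          "additionalProperties": {"$ref": "#/$defs/hand_model"}
        }
      }
    }
  ],
  "$defs": {
    "hand_model": {
      "type": "object",
      "required": ["handedness", "palm_normal", "landmarks"],
      "properties": {
        "handedness": {"enum": ["left", "right"]},
        "palm_normal": {
          "type": "array", "items": {"type": "number"},
          "minItems": 3, "maxItems": 3,
          "description": "unit vector orthogonal to the palm"
        },
        "landmarks": {
          "type": "object",
          "minProperties": 25,
          "maxProperties": 25,
          "additionalProperties": {
            "type": "object",
            "required": ["p"],
            "properties": {
              "p": {
                "type": "array", "items": {"type": "number"},
                "minItems": 3, "maxItems": 3,
                "description": "position [mm]"
              },
              "r": {
                "type": "number", "minimum": 0, "maximum": 1,
                "description": "per-joint tracking reliability"
              }
            }
          }
        }
      }
    }
  }
}
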