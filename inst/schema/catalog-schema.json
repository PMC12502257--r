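{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "vmrasat catalog file (YAML, schema_version 1)",
  "type": "object",
  "additionalProperties": false,
  "required": ["schema_version", "profile", "scale", "algorithms", "indicators", "functions"],
  "properties": {
    "schema_version": {"const": 1},
    "profile": {"type": "string", "minLength": 1},
    "title": {"type": "string"},
    "version": {"type": ["string", "number"]},
    "scale": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["rating", "score"],
        "properties": {
          "rating": {"type": "string"},
          "score": {"type": "number", "minimum": 0, "maximum": 1,
                    "description": "multiple of 0.25; IMPLEMENTED must be 1, NOT_IMPLEMENTED 0; NOT_APPLICABLE is implicit and never scored"}
        }
      }
    },
    "algorithms": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": false,
        "required": ["requires_critical", "tiers"],
        "properties": {
          "requires_critical": {"type": "boolean"},
          "tiers": {
            "type": "array",
            "items": {
              "type": "object",
              "additionalProperties": false,
              "required": ["tier", "min_implemented", "max_partial", "max_not_implemented",
                           "lower_tiers_full", "pooled_with_lower"],
              "properties": {
                "tier": {"type": "string"},
                "min_implemented": {"type": "string", "pattern": "^[0-9]+/[0-9]+$"},
                "max_partial": {"type": "string", "pattern": "^[0-9]+/[0-9]+$"},
                "max_not_implemented": {"type": "string", "pattern": "^[0-9]+/[0-9]+$"},
                "lower_tiers_full": {"type": "boolean"},
                "pooled_with_lower": {"type": "boolean"}
              }
            }
          }
        }
      }
    },
    "indicators": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["indicator_code", "name"],
        "properties": {
          "indicator_code": {"type": "string"},
          "name": {"type": "string"}
        }
      }
    },
    "functions": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["function_code", "name"],
        "properties": {
          "function_code": {"type": "string"},
          "name": {"type": "string"},
          "sub_indicators": {
            "type": "array",
            "items": {
              "type": "object",
              "additionalProperties": false,
              "required": ["sub_id", "indicator_code", "tier"],
              "properties": {
                "sub_id": {"type": "string"},
                "indicator_code": {"type": "string"},
                "tier": {"type": "string"},
                "critical": {"type": "boolean"},
                "institution_mandatory": {"type": "boolean"},
                "text": {"type": "string"}
              }
            }
          }
        }
      }
    },
    "declared_totals": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "total": {"type": "integer"},
        "tiers": {"type": "object", "additionalProperties": {"type": "integer"}}
      }
    }
  }
}
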