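{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "vmrasat JSON report",
  "type": "object",
  "additionalProperties": false,
  "required": ["metadata", "functions", "institution", "idp_summary"],
  "properties": {
    "metadata": {
      "type": "object",
      "additionalProperties": false,
      "required": ["agency", "profile", "catalog_version", "algorithm"],
      "properties": {
        "agency": {"type": "string"},
        "date": {"type": ["string", "null"]},
        "profile": {"type": "string"},
        "catalog_version": {"type": "string"},
        "algorithm": {"type": "string"}
      }
    },
    "functions": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["function_code", "name", "score", "score_rational",
                     "applicable_count", "achieved_tier", "qualifier", "shortfalls", "tally"],
        "properties": {
          "function_code": {"type": "string"},
          "name": {"type": "string"},
          "score": {"type": ["number", "null"]},
          "score_rational": {
            "type": "object",
            "additionalProperties": false,
            "properties": {
              "num": {"type": ["integer", "null"]},
              "den": {"type": ["integer", "null"]}
            }
          },
          "applicable_count": {"type": "integer"},
          "achieved_tier": {"type": "string"},
          "qualifier": {"type": "string"},
          "shortfalls": {
            "type": "array",
            "items": {
              "type": "object",
              "additionalProperties": false,
              "properties": {
                "tier": {"type": "string"},
                "constraint": {"type": "string"},
                "required": {"type": "string"},
                "observed": {"type": "string"}
              }
            }
          },
          "tally": {
            "type": "array",
            "items": {
              "type": "object",
              "additionalProperties": false,
              "properties": {
                "tier": {"type": "string"},
                "implemented_n": {"type": "integer"},
                "partial_n": {"type": "integer"},
                "ongoing_n": {"type": "integer"},
                "not_implemented_n": {"type": "integer"},
                "applicable_n": {"type": "integer"}
              }
            }
          }
        }
      }
    },
    "institution": {
      "type": "object",
      "additionalProperties": false,
      "required": ["tier", "qualifier", "mandatory_failures"],
      "properties": {
        "tier": {"type": "string"},
        "qualifier": {"type": "string"},
        "mandatory_failures": {"type": "array", "items": {"type": "string"}}
      }
    },
    "idp_summary": {
      "type": "object",
      "additionalProperties": false,
      "required": ["total", "by_tier"],
      "properties": {
        "total": {"type": "integer"},
        "by_tier": {"type": "object", "additionalProperties": {"type": "integer"}}
      }
    }
  }
}
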