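{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ofmdiff native enzyme-constrained model",
  "type": "object",
  "required": ["metabolites", "reactions", "genes", "objective"],
  "$defs": {
    "scalarOrParam": {
      "oneOf": [
        {"type": "number"},
        {"type": "string", "const": "Inf"},
        {
          "type": "object",
          "required": ["param"],
          "properties": {"param": {"type": "string", "minLength": 1}},
          "additionalProperties": false
        }
      ]
    }
  },
  "properties": {
    "id": {"type": "string"},
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "compartment": {"type": ["string", "null"]}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "stoichiometry"],
        "properties": {
          "id": {"type": "string"},
          "stoichiometry": {
            "type": "object",
            "additionalProperties": {"type": "number"},
            "minProperties": 1
          },
          "lower_bound": {"$ref": "#/$defs/scalarOrParam"},
          "upper_bound": {"$ref": "#/$defs/scalarOrParam"},
          "objective_coefficient": {"type": "number"},
          "isozymes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["subunit_counts"],
              "properties": {
                "subunit_counts": {
                  "type": "object",
                  "additionalProperties": {"type": "integer", "minimum": 1},
                  "minProperties": 1
                },
                "kcat_forward": {"$ref": "#/$defs/scalarOrParam"},
                "kcat_reverse": {
                  "oneOf": [{"$ref": "#/$defs/scalarOrParam"},
                            {"type": "null"}]
                }
              }
            }
          }
        }
      }
    },
    "genes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "molar_mass"],
        "properties": {
          "id": {"type": "string"},
          "molar_mass": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    },
    "pools": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "members", "capacity"],
        "properties": {
          "id": {"type": "string"},
          "members": {
            "type": "array",
            "items": {"type": "string"},
            "minItems": 1
          },
          "capacity": {"$ref": "#/$defs/scalarOrParam"}
        }
      }
    },
    "fixed_fluxes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["reaction_id", "value"],
        "properties": {
          "reaction_id": {"type": "string"},
          "value": {"$ref": "#/$defs/scalarOrParam"}
        }
      }
    },
    "objective": {"type": "string"}
  }
}
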