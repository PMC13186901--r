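{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "renaltwin arterial network file",
  "type": "object",
  "required": ["inlet", "vessels", "terminals"],
  "properties": {
    "inlet": {
      "type": "object",
      "required": ["vessel"],
      "properties": {
        "vessel": {"type": "string"},
        "waveform_ref": {"type": "string"}
      }
    },
    "vessels": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "length_mm", "radius_mm", "wall_thickness_mm", "youngs_modulus_kPa"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "parent": {"type": "string"},
          "region": {"enum": ["systemic", "renal"]},
          "generation": {"enum": ["main", "segmental", "interlobar", "arcuate"]},
          "length_mm": {"type": "number", "exclusiveMinimum": 0},
          "radius_mm": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 50},
          "wall_thickness_mm": {"type": "number", "exclusiveMinimum": 0},
          "youngs_modulus_kPa": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    },
    "terminals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["vessel", "R1", "R2", "C"],
        "properties": {
          "vessel": {"type": "string"},
          "type": {"enum": ["windkessel", "bed"]},
          "R1": {"type": "number", "exclusiveMinimum": 0,
                 "description": "proximal terminal resistance, Pa s/m^3"},
          "R2": {"type": "number", "exclusiveMinimum": 0,
                 "description": "distal terminal resistance, Pa s/m^3"},
          "C": {"type": "number", "exclusiveMinimum": 0,
                "description": "terminal compliance, m^3/Pa"}
        }
      }
    }
  }
}
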