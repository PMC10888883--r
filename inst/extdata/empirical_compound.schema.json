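{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "EmpiricalCompoundSet",
  "description": "Array of empirical compounds: groups of degenerate LC-MS features (isotopologues x adducts) with inferred neutral mass and a chained annotation list. Masses in Da, retention times in seconds.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["interim_id", "neutral_formula_mass", "neutral_formula",
                 "charge_sign", "MS1_pseudo_Spectra", "MS2_Spectra",
                 "annotations"],
    "properties": {
      "interim_id": {"type": "string"},
      "neutral_formula_mass": {"type": ["number", "null"]},
      "neutral_formula": {"type": ["string", "null"]},
      "charge_sign": {"enum": [1, -1]},
      "MS1_pseudo_Spectra": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["feature_id", "mz", "rtime", "isotope", "modification"],
          "properties": {
            "feature_id": {"type": "string"},
            "mz": {"type": "number", "exclusiveMinimum": 0},
            "rtime": {"type": "number", "minimum": 0},
            "isotope": {"type": "string"},
            "modification": {"type": "string"}
          }
        }
      },
      "MS2_Spectra": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["precursor_mz", "retention_time", "source_acquisition",
                       "peaks"],
          "properties": {
            "precursor_mz": {"type": "number"},
            "retention_time": {"type": ["number", "null"]},
            "source_acquisition": {"type": ["string", "null"]},
            "peaks": {
              "type": "array",
              "items": {
                "type": "array",
                "prefixItems": [{"type": "number"}, {"type": "number"}],
                "minItems": 2, "maxItems": 2
              }
            }
          }
        }
      },
      "annotations": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["level", "compound_name", "identifiers", "score",
                       "source", "evidence"],
          "properties": {
            "level": {"enum": ["1a", "1b", "2", "4"]},
            "compound_name": {"type": "string"},
            "identifiers": {"type": "object"},
            "score": {"type": ["number", "null"]},
            "source": {"type": "string"},
            "evidence": {"type": "object"}
          }
        }
      }
    }
  }
}
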