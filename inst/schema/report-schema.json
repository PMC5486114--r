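{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "stdnmr pipeline report",
  "type": "object",
  "required": ["mode", "seed", "ic50", "ic50_units", "n_points"],
  "properties": {
    "mode": {"type": "string"},
    "seed": {"type": "integer"},
    "ic50": {"type": "number"},
    "ic50_units": {"type": "string"},
    "se": {"type": "number"},
    "n_points": {"type": "integer"},
    "stages": {"type": "object"}
  }
}
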