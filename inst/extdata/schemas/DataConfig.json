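{
  "$id": "DataConfig.json",
  "title": "DataConfig",
  "description": "Summary configuration for one data version: anatomical areas, base path prefixes, and the constants table used to interpolate long common values into documents as short @keys.",
  "type": "object",
  "required": ["anatomicalAreas", "constants", "prefixes", "version"],
  "properties": {
    "anatomicalAreas": { "type": "array", "items": { "type": "string" } },
    "constants": { "type": "object" },
    "prefixes": { "type": "object" },
    "version": { "type": "string" }
  }
}
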