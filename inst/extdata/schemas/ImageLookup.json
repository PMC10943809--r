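{
  "$id": "ImageLookup.json",
  "title": "ImageLookup",
  "description": "Lookup result for a body id or driver line id: the list of neuron images registered under that identifier.",
  "type": "object",
  "required": ["results"],
  "properties": {
    "results": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "libraryName", "alignmentSpace", "publishedName", "modality", "files"],
        "properties": {
          "id": { "type": "string" },
          "libraryName": { "type": "string" },
          "alignmentSpace": { "type": "string" },
          "publishedName": { "type": "string" },
          "sampleId": { "type": "string" },
          "modality": { "type": "string", "enum": ["EM", "LM"] },
          "files": {
            "type": "object",
            "required": ["CDM"],
            "properties": {
              "CDM": { "type": "string" },
              "CDMInput": { "type": "string" }
            }
          }
        }
      }
    }
  }
}
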