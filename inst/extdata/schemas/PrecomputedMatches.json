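{
  "$id": "PrecomputedMatches.json",
  "title": "PrecomputedMatches",
  "description": "Precomputed match list for one input image. Image metadata is denormalized into each result so a client needs a single request. The same document shape serves any matching algorithm; pixel-overlap results carry matchingPixels and the shape ratio score.",
  "type": "object",
  "required": ["inputImage", "results"],
  "properties": {
    "inputImage": {
      "type": "object",
      "required": ["id", "libraryName", "alignmentSpace", "publishedName", "modality", "files"],
      "properties": {
        "id": { "type": "string" },
        "modality": { "type": "string", "enum": ["EM", "LM"] }
      }
    },
    "results": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["image", "mirrored", "matchingPixels", "normalizedScore"],
        "properties": {
          "image": {
            "type": "object",
            "required": ["id", "libraryName", "alignmentSpace", "publishedName", "modality", "files"],
            "properties": {
              "id": { "type": "string" },
              "modality": { "type": "string", "enum": ["EM", "LM"] }
            }
          },
          "mirrored": { "type": "boolean" },
          "matchingPixels": { "type": "integer" },
          "gradientAreaGap": { "type": "integer" },
          "shapeScore": { "type": "number" },
          "normalizedScore": { "type": "number" }
        }
      }
    }
  }
}
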