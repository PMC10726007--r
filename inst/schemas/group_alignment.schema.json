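{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "group_alignment",
  "type": "object",
  "required": ["group_id", "group_provenance", "reference", "members"],
  "properties": {
    "group_id": { "type": "string" },
    "group_provenance": {
      "type": "object",
      "required": ["method", "granularity", "software_name", "description", "version"],
      "properties": {
        "method": {
          "type": "string",
          "enum": ["deposition", "reference_accession", "sequence_identity"]
        },
        "granularity": { "type": "string", "enum": ["entry", "entity"] }
      }
    },
    "reference": {
      "type": "object",
      "required": ["id", "sequence", "n_columns"],
      "properties": {
        "id": { "type": "string" },
        "sequence": { "type": "string" },
        "n_columns": { "type": "integer" }
      }
    },
    "members": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["member_uid", "aligned_regions"],
        "properties": {
          "member_uid": { "type": "string" },
          "aligned_regions": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["member_begin", "member_end", "column_begin", "column_end"],
              "properties": {
                "member_begin": { "type": "integer" },
                "member_end": { "type": "integer" },
                "column_begin": { "type": "integer" },
                "column_end": { "type": "integer" }
              }
            }
          }
        }
      }
    },
    "consensus": { "type": "array", "items": { "type": ["string", "null"] } },
    "variation": { "type": "array", "items": { "type": ["number", "null"] } }
  }
}
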