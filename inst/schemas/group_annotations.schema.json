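{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "group_annotations",
  "type": "object",
  "required": ["group_id", "mode", "annotations"],
  "properties": {
    "group_id": { "type": "string" },
    "mode": { "type": "string", "enum": ["per_member", "histogram"] },
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "track_id": { "type": "string" },
          "kind": {
            "type": "string",
            "enum": ["symbol", "fraction", "count", "region", "score"]
          },
          "values": { "type": "array" },
          "member_uid": { "type": "string" },
          "features": { "type": "array" },
          "aligned_regions": { "type": "array" }
        }
      }
    }
  }
}
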