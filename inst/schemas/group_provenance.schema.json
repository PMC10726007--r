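{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "group_provenance",
  "type": "object",
  "required": ["method", "granularity", "software_name", "description", "version"],
  "properties": {
    "method": {
      "type": "string",
      "enum": ["deposition", "reference_accession", "sequence_identity"]
    },
    "granularity": { "type": "string", "enum": ["entry", "entity"] },
    "software_name": { "type": "string" },
    "description": { "type": "string" },
    "version": { "type": "string" }
  }
}
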