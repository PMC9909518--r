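# Example exclusion-rule configuration: entries matching a rule are
# non-medication orders and are removed before ATC mapping.
rules:
- id: bga
  kind: prefix
  pattern: BGA
  description: laboratory request for blood gas analysis
- id: be
  kind: prefix
  pattern: BE
  description: request to nurses for taking a blood sample
- id: bb
  kind: prefix
  pattern: BB
  description: laboratory request for blood count
- id: lab
  kind: regex
  pattern: "^Labor[: ]"
  description: free-form laboratory order
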