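# Example configuration: the original 75:25 design paid on the calendar
# actually observed during implementation. Unspecified keys keep their
# documented defaults (see ?default_config).
p4p:
  enabled: true
  schedule: actual_delayed
  staff_share: 0.75
commodities:
  msd_fulfilment: 0.75
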