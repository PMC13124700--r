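# Example pipeline configuration: a small spontaneous-report database with a
# five-fold elevated pemphigoid reporting rate for ofloxacin.
simulate:
  n_reports: 20000
  base_rate: 0.01
  duplicate_fraction: 0.1
  relative_risk:
    CIPROFLOXACIN: 1
    LEVOFLOXACIN: 1
    MOXIFLOXACIN: 1
    NORFLOXACIN: 1
    OFLOXACIN: 5
event_terms: Pemphigoid
stratify:
  - sex
  - age
  - reporter
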