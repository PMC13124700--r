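drug,age_years,sex,latency_days,hospitalized,outcome
CIPROFLOXACIN,72,F,18,TRUE,recovered after withdrawal
CIPROFLOXACIN,67,M,4,FALSE,recovered
CIPROFLOXACIN,38,F,10,TRUE,recovered after withdrawal
LEVOFLOXACIN,78,F,21,TRUE,recovered after withdrawal
LEVOFLOXACIN,70,M,30,FALSE,recovered
OFLOXACIN,81,F,14,TRUE,recovered after withdrawal
OFLOXACIN,58,M,24,FALSE,recovered
MOXIFLOXACIN,84,F,7,TRUE,recovered after withdrawal
NORFLOXACIN,75,M,28,FALSE,recovered
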