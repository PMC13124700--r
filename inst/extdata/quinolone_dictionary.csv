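canonical,synonyms,approval_date,include
CIPROFLOXACIN,CIPRO;CIPRO XR;CIPROXIN;CIPROFLOXACIN HYDROCHLORIDE,19871022,TRUE
LEVOFLOXACIN,LEVAQUIN;TAVANIC;LEVOFLOXACIN HEMIHYDRATE,19961220,TRUE
MOXIFLOXACIN,AVELOX;MOXIFLOXACIN HYDROCHLORIDE,19991210,TRUE
NORFLOXACIN,NOROXIN;NORFLOXACIN SANDOZ,19861031,TRUE
OFLOXACIN,FLOXIN;OFLOXACIN OTIC;TARIVID,19901228,TRUE
GATIFLOXACIN,TEQUIN;ZYMAR,19991217,FALSE
GEMIFLOXACIN,FACTIVE,20030404,FALSE
ENOXACIN,PENETREX,19911231,FALSE
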