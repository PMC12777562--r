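component,arm,no_event,event
Absence of clinical success,doripenem,293,81
Absence of clinical success,levofloxacin,261,113
Infectious complications,doripenem,351,23
Infectious complications,levofloxacin,369,5
Non-fatal SAEs,doripenem,349,25
Non-fatal SAEs,levofloxacin,360,14
Death,doripenem,373,1
Death,levofloxacin,374,0
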