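arm,Alive with no events,Alive with 1 event,Alive with 2 events,Alive with 3 events,Death
doripenem,263,93,16,1,1
levofloxacin,253,111,9,1,0
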