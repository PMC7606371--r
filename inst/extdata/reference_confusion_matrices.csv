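variant,level,actual,pass,questionable,fail
dsr,volume,pass,1254,892,2
dsr,volume,questionable,132,1000,38
dsr,volume,fail,10,62,234
dsr,subject,pass,4,6,0
dsr,subject,questionable,1,9,0
dsr,subject,fail,0,1,3
dsr_nlr,volume,pass,1569,579,0
dsr_nlr,volume,questionable,63,1102,5
dsr_nlr,volume,fail,18,66,222
dsr_nlr,subject,pass,7,3,0
dsr_nlr,subject,questionable,1,9,0
dsr_nlr,subject,fail,0,1,3
nldr_nlr,volume,pass,1952,196,0
nldr_nlr,volume,questionable,33,1135,2
nldr_nlr,volume,fail,0,15,291
nldr_nlr,subject,pass,9,1,0
nldr_nlr,subject,questionable,0,10,0
nldr_nlr,subject,fail,0,0,4
dsr_nldr_nlr,volume,pass,2134,14,0
dsr_nldr_nlr,volume,questionable,23,1147,0
dsr_nldr_nlr,volume,fail,0,0,306
dsr_nldr_nlr,subject,pass,10,0,0
dsr_nldr_nlr,subject,questionable,0,10,0
dsr_nldr_nlr,subject,fail,0,0,4
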