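interval,ppl
"[0,1]",1526.11
"[0.5,1]",1561.95
"[0,0.5)",1549.54
"[0.2,0.5)",1496.20
"[0,0.2)",1533.52
"[0.1,0.2)",1482.50
"[0,0.1)",1559.26
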