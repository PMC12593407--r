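"id","role","d1","d2"
"A-ala","acid",1.2417,0.3216
"A-indanyl","amine",1.6523,-0.8867
"A-mbn","amine",0.2968,-0.0076
"A-mex","amine",0.6812,0.1755
"C-chx","acid",-0.8538,0.9276
"C-ala","acid",1.8698,0.7609
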