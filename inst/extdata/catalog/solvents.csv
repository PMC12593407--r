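"id","d1","d2","d3"
"THF",-1.2621,-0.6724,0.4482
"2-MeTHF",-2.0271,1.6732,-1.8778
"dioxane",0.8345,-0.4646,0.176
"DME",1.0056,-0.7464,0.8935
"diglyme",1.9646,0.254,-1.0692
"DMA",-1.2611,1.6527,-0.3355
"NMP",-0.2588,0.5277,-0.3198
"MeCN",0.3659,0.1756,-1.3498
"EtOAc",-0.0154,0.4246,0.201
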