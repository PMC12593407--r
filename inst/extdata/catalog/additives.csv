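"id","cation","anion"
"none","none","none"
"MgCl2","Mg","Cl"
"MgBr2","Mg","Br"
"MgI2","Mg","I"
"ZnCl2","Zn","Cl"
"ZnBr2","Zn","Br"
"LiCl","Li","Cl"
"LiBr","Li","Br"
"NaI","Na","I"
"NaBr","Na","Br"
"KBr","K","Br"
"KI","K","I"
"TMSCl","TMS","Cl"
"NBu4Br","NBu4","Br"
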