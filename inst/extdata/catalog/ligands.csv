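"id","d1","d2","d3","d4"
"L1",0.7539,1.945,-0.4661,-1.1414
"L2",-1.1536,-0.8211,-3.1099,0.835
"L3",-2.265,-0.2686,0.3113,-0.1229
"L4",0.2849,1.0056,1.37,0.3007
"L5",-1.7846,0.0759,-3e-04,0.5565
"L6",1.6414,0.6037,-0.2092,1.2197
"L7",0.1439,0.2685,-0.8552,0.3158
"L8",0.1383,0.5161,1.0333,-0.6197
"L9",0.9008,0.782,1.061,-1.1306
"L10",0.6042,-0.5378,2.2108,-0.3766
"L11",-0.7506,1.0051,1.7583,-0.1288
"L12",0.5515,-0.0588,-0.017,-0.3964
"L13",2.3171,0.1018,0.4033,-0.5221
"L14",1.0501,-0.1134,0.0544,1.142
"L15",1.4639,-0.451,1.4538,1.6284
"L16",0.2179,-1.4946,0.4699,0.6201
"L17",-0.6305,-0.1448,0.0564,1.6937
"L18",-1.0279,1.4412,-2.4409,0.2278
"L19",1.119,-0.0779,-0.0724,-0.0778
"L20",-0.8774,-0.1319,1.7843,-0.2761
"L21",-0.7693,0.4234,-0.2473,0.1648
"L22",0.9019,-0.6662,-0.0401,0.2247
"L23",0.8418,-0.7883,-1.0869,1.1754
"L24",0.8653,0.7025,-0.4267,-0.9373
"L25",-0.3425,1.0507,-0.4525,0.1426
"L26",-0.9812,0.459,-1.6739,-0.5159
"L27",-2.1395,-0.6787,0.0949,0.5344
"L28",0.0416,0.485,-0.0721,-1.6409
"L29",0.8719,0.9088,1.4441,-0.5645
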