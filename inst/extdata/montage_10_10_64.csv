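"channel","x","y"
"Fp1",-0.31,0.95
"Fpz",0,0.95
"Fp2",0.31,0.95
"AF7",-0.55,0.78
"AF3",-0.25,0.78
"AFz",0,0.78
"AF4",0.25,0.78
"AF8",0.55,0.78
"F7",-0.81,0.55
"F5",-0.59,0.55
"F3",-0.4,0.55
"F1",-0.2,0.55
"Fz",0,0.55
"F2",0.2,0.55
"F4",0.4,0.55
"F6",0.59,0.55
"F8",0.81,0.55
"FT7",-0.92,0.28
"FC5",-0.67,0.28
"FC3",-0.45,0.28
"FC1",-0.22,0.28
"FCz",0,0.28
"FC2",0.22,0.28
"FC4",0.45,0.28
"FC6",0.67,0.28
"FT8",0.92,0.28
"T7",-1,0
"C5",-0.75,0
"C3",-0.5,0
"C1",-0.25,0
"Cz",0,0
"C2",0.25,0
"C4",0.5,0
"C6",0.75,0
"T8",1,0
"TP7",-0.92,-0.28
"CP5",-0.67,-0.28
"CP3",-0.45,-0.28
"CP1",-0.22,-0.28
"CPz",0,-0.28
"CP2",0.22,-0.28
"CP4",0.45,-0.28
"CP6",0.67,-0.28
"TP8",0.92,-0.28
"P9",-1,-0.55
"P7",-0.81,-0.55
"P5",-0.59,-0.55
"P3",-0.4,-0.55
"P1",-0.2,-0.55
"Pz",0,-0.55
"P2",0.2,-0.55
"P4",0.4,-0.55
"P6",0.59,-0.55
"P8",0.81,-0.55
"P10",1,-0.55
"PO7",-0.55,-0.78
"PO3",-0.25,-0.78
"POz",0,-0.78
"PO4",0.25,-0.78
"PO8",0.55,-0.78
"O1",-0.31,-0.95
"Oz",0,-0.95
"O2",0.31,-0.95
"Iz",0,-1.08
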