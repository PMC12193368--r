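"id","treatment","sex","egg_entry","nymph_entry","pupa_entry","adult_entry","death_age"
"dsEGFP-like_001","dsEGFP-like","female",0,6,13,19,52
"dsEGFP-like_002","dsEGFP-like","undetermined",0,4,12,,17
"dsEGFP-like_003","dsEGFP-like","male",0,5,14,19,32
"dsEGFP-like_004","dsEGFP-like","female",0,4,13,18,76
"dsEGFP-like_005","dsEGFP-like","male",0,3,11,17,44
"dsEGFP-like_006","dsEGFP-like","male",0,5,10,15,48
"dsEGFP-like_007","dsEGFP-like","undetermined",0,5,16,,17
"dsEGFP-like_008","dsEGFP-like","male",0,6,13,19,77
"dsEGFP-like_009","dsEGFP-like","female",0,5,11,17,59
"dsEGFP-like_010","dsEGFP-like","undetermined",0,5,10,,11
"dsEGFP-like_011","dsEGFP-like","male",0,4,12,18,28
"dsEGFP-like_012","dsEGFP-like","female",0,4,11,16,50
"dsEGFP-like_013","dsEGFP-like","male",0,3,9,15,42
"dsEGFP-like_014","dsEGFP-like","female",0,3,14,20,81
"dsEGFP-like_015","dsEGFP-like","undetermined",0,5,14,,17
"dsEGFP-like_016","dsEGFP-like","male",0,5,16,22,64
"dsEGFP-like_017","dsEGFP-like","male",0,4,10,16,74
"dsEGFP-like_018","dsEGFP-like","female",0,5,11,16,31
"dsEGFP-like_019","dsEGFP-like","female",0,4,11,17,60
"dsEGFP-like_020","dsEGFP-like","female",0,6,15,20,80
"dsEGFP-like_021","dsEGFP-like","male",0,5,12,18,89
"dsEGFP-like_022","dsEGFP-like","female",0,6,14,20,64
"dsEGFP-like_023","dsEGFP-like","male",0,4,14,19,35
"dsEGFP-like_024","dsEGFP-like","female",0,4,13,17,77
"dsEGFP-like_025","dsEGFP-like","female",0,4,11,16,50
"dsEGFP-like_026","dsEGFP-like","female",0,4,10,16,126
"dsEGFP-like_027","dsEGFP-like","female",0,4,10,15,45
"dsEGFP-like_028","dsEGFP-like","female",0,4,15,21,57
"dsEGFP-like_029","dsEGFP-like","male",0,3,9,15,57
"dsEGFP-like_030","dsEGFP-like","female",0,4,11,16,63
"dsEGFP-like_031","dsEGFP-like","female",0,5,11,16,48
"dsEGFP-like_032","dsEGFP-like","undetermined",0,4,,,7
"dsEGFP-like_033","dsEGFP-like","male",0,3,7,12,43
"dsEGFP-like_034","dsEGFP-like","male",0,5,9,13,84
"dsEGFP-like_035","dsEGFP-like","female",0,5,14,19,58
"dsEGFP-like_036","dsEGFP-like","male",0,4,8,13,85
"dsEGFP-like_037","dsEGFP-like","male",0,4,11,17,23
"dsEGFP-like_038","dsEGFP-like","undetermined",0,5,,,7
"dsEGFP-like_039","dsEGFP-like","male",0,5,11,17,54
"dsEGFP-like_040","dsEGFP-like","female",0,5,17,23,77
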