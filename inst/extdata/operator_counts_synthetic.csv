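specimen,op1,op2,op3,op4,op5
S01,50,50,50,50,50
S02,50,50,50,50,50
S03,50,50,50,50,50
S04,50,50,50,50,50
S05,50,50,50,50,50
S06,50,50,50,50,50
S07,50,50,50,50,50
S08,50,50,50,50,50
S09,50,50,50,50,50
S10,50,50,50,50,50
S11,50,50,50,50,50
S12,50,50,50,50,50
S13,50,50,50,50,50
S14,50,50,50,50,50
S15,50,50,50,50,50
S16,50,50,50,50,50
S17,50,50,50,50,50
S18,50,50,50,50,50
S19,50,50,50,50,50
S20,50,50,50,50,50
S21,50,50,50,50,50
S22,50,50,50,50,50
S23,50,50,50,50,50
S24,50,50,50,50,50
S25,50,50,50,50,50
S26,50,50,50,2,50
S27,50,50,50,2,50
S28,50,50,50,2,50
S29,2,2,2,2,2
S30,2,2,2,2,2
S31,2,2,2,2,2
S32,2,2,2,2,2
S33,2,2,2,2,2
S34,2,2,2,2,2
S35,2,2,2,2,2
S36,2,2,2,2,2
S37,2,2,2,2,2
S38,2,2,2,2,2
S39,2,2,2,2,2
S40,2,2,2,2,2
S41,2,2,2,2,2
S42,2,2,2,2,2
S43,2,2,2,2,2
S44,2,2,2,2,2
S45,2,2,2,2,2
S46,2,2,2,2,2
S47,2,2,2,2,2
S48,2,2,2,2,2
S49,2,2,2,2,2
S50,2,2,2,2,2
S51,2,2,2,2,2
S52,2,2,2,2,2
S53,2,2,2,2,2
S54,2,2,2,2,2
S55,2,2,2,2,2
S56,2,2,2,2,2
S57,2,2,2,2,2
S58,2,2,2,2,2
S59,2,2,2,2,2
S60,2,2,2,2,2
S61,2,2,2,2,2
S62,2,2,2,2,2
S63,2,2,2,2,2
S64,2,2,2,50,2
S65,2,2,2,50,2
S66,2,2,2,50,2
S67,2,2,2,50,2
S68,2,2,2,50,2
S69,2,2,2,50,2
S70,2,2,2,50,2
S71,2,2,2,50,2
S72,2,2,2,50,2
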