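child_id,grade,age_months,math_score,language_score,avg_past_score
c01,KG,58,5,,2.65
c02,KG,55,5,5,2.27
c03,KG,60,2,3,0.77
c04,KG,58,5,5,2.55
c05,KG,55,5,4,2.45
c06,1,64,4,5,2.31
c07,1,64,5,5,2.56
c08,1,69,4,4,2.42
c09,1,76,4,4,2.27
c10,1,69,3,3,1.98
c11,1,73,4,4,2.75
c12,1,71,5,5,2.79
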