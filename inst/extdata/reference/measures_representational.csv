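child_id,grade,pct_rr,lam_v,lam_h,tt_v,tt_h,maxl_v,maxl_h
c01,KG,33.1,0.316,0.315,3.1,3.9,5,7
c02,KG,70.7,0.707,0.660,5.8,4.7,9,10
c03,KG,0.7,0.007,0.000,3.0,0.0,3,1
c04,KG,92.8,0.928,0.837,7.5,5.3,26,11
c05,KG,26.7,0.160,0.229,3.0,3.0,3,5
c06,1,4.4,0.042,0.030,4.8,4.0,7,4
c07,1,68.5,0.671,0.674,5.3,4.4,11,12
c08,1,26.1,0.252,0.145,7.0,3.3,12,5
c09,1,70.2,0.702,0.657,5.8,5.9,10,10
c10,1,39.7,0.397,0.250,8.2,5.7,25,8
c11,1,79.5,0.767,0.530,5.6,2.7,18,3
c12,1,80.2,0.802,0.632,9.8,3.7,24,6
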