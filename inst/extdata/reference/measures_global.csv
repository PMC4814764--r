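child_id,grade,q_los,rr_peak,tau_peak,rr,lam_v,lam_h,tt_v,tt_h,maxl_v,maxl_h
c01,KG,0.46,0.056,18,0.013,0.986,0.910,5.2,3.4,21,7
c02,KG,0.58,0.089,16,0.019,0.996,0.885,6.4,3.8,19,10
c03,KG,0.91,0.015,,0.004,0.968,0.687,4.3,2.6,12,3
c04,KG,0.98,0.076,2,0.011,1.000,0.885,7.4,5.1,26,11
c05,KG,1.31,0.012,36,0.002,0.893,0.901,3.2,3.1,5,6
c06,1,1.28,0.034,-1,0.010,0.957,0.701,6.6,2.6,16,5
c07,1,0.48,0.039,-1,0.009,0.979,0.922,5.8,4.0,18,12
c08,1,1.65,0.034,0,0.006,0.973,0.624,4.8,2.8,12,5
c09,1,0.90,0.140,0,0.025,0.992,0.924,6.3,5.1,15,15
c10,1,0.92,0.053,-1,0.016,1.000,0.789,6.0,5.5,25,27
c11,1,1.78,0.021,-1,0.002,0.959,0.632,5.4,2.7,18,3
c12,1,1.66,0.073,-1,0.018,1.000,0.793,8.3,3.6,24,6
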