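child_id,grade,pct_rr,lam_v,lam_h,tt_v,tt_h,maxl_v,maxl_h
c01,KG,66.9,0.669,0.595,7.6,3.2,21,7
c02,KG,29.3,0.289,0.226,8.3,2.5,19,3
c03,KG,99.3,0.961,0.687,4.3,2.3,12,3
c04,KG,7.2,0.072,0.048,6.0,3.2,6,7
c05,KG,73.3,0.733,0.672,3.2,3.1,5,6
c06,1,95.6,0.915,0.672,6.7,2.6,16,5
c07,1,31.5,0.308,0.248,7.0,3.3,18,5
c08,1,73.9,0.721,0.480,4.3,2.7,8,4
c09,1,29.8,0.290,0.267,7.6,3.9,15,15
c10,1,60.3,0.603,0.539,5.1,5.4,10,27
c11,1,20.5,0.192,0.103,4.7,3.0,10,3
c12,1,19.8,0.198,0.161,5.0,3.3,9,5
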