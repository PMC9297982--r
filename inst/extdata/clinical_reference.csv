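population,roi,time_years,measure,mean,sd,n
fe,medial,-0.04,bmd_preop,0.594,0.162,26
fe,lateral,-0.04,bmd_preop,0.466,0.084,26
fe,distal,-0.04,bmd_preop,0.701,0.160,26
clinical,medial,-0.04,bmd_preop,0.854,0.311,17
clinical,lateral,-0.04,bmd_preop,0.544,0.147,17
clinical,distal,-0.04,bmd_preop,0.656,0.140,17
clinical,medial,0,bmd,1.166,0.282,17
clinical,lateral,0,bmd,0.899,0.190,17
clinical,distal,0,bmd,0.897,0.314,17
clinical,medial,2,bmd,0.649,0.127,17
clinical,lateral,2,bmd,0.646,0.156,17
clinical,distal,2,bmd,0.749,0.172,17
clinical,medial,2,delta_rel,-41.6,16.0,17
clinical,lateral,2,delta_rel,-26.3,17.6,17
clinical,distal,2,delta_rel,-13.0,16.7,17
clinical,medial,2,delta_abs,-0.517,0.281,17
clinical,lateral,2,delta_abs,-0.253,0.205,17
clinical,distal,2,delta_abs,-0.148,0.232,17
clinical,medial,5,bmd,0.768,0.287,17
clinical,lateral,5,bmd,0.709,0.190,17
clinical,distal,5,bmd,0.764,0.132,17
clinical,medial,5,delta_rel,-34.2,25.8,17
clinical,lateral,5,delta_rel,-18.1,21.0,17
clinical,distal,5,delta_rel,-12.3,23.6,17
clinical,medial,5,delta_abs,-0.451,0.372,17
clinical,lateral,5,delta_abs,-0.175,0.203,17
clinical,distal,5,delta_abs,-0.181,0.313,17
clinical,medial,11.6,bmd,0.608,0.183,17
clinical,lateral,11.6,bmd,0.700,0.284,17
clinical,distal,11.6,bmd,0.711,0.118,17
clinical,medial,11.6,delta_rel,-47.3,13.3,17
clinical,lateral,11.6,delta_rel,-19.6,36.0,17
clinical,distal,11.6,delta_rel,-16.0,16.6,17
clinical,medial,11.6,delta_abs,-0.558,0.219,17
clinical,lateral,11.6,delta_abs,-0.199,0.301,17
clinical,distal,11.6,delta_abs,-0.187,0.255,17
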