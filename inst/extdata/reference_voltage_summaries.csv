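surface,segment_id,region,rv_surrogate,mean_healthy,sd_healthy,mean_postmi_novt,sd_postmi_novt,mean_postmi_vt,sd_postmi_vt,mean_hcm,sd_hcm,n_per_group,p_reported
ENDO,1,Basal anterior,FALSE,802,108,853,281,982,230,1086,241,10,0.016
ENDO,2,Basal anteroseptal,FALSE,812,128,931,304,954,166,1085,266,10,0.043
ENDO,3,Basal inferoseptal,FALSE,829,103,901,359,943,318,1121,239,10,0.071
ENDO,4,Basal inferior,FALSE,823,106,804,275,942,241,1037,276,10,0.130
ENDO,5,Basal inferolateral,FALSE,856,98,835,291,958,209,1081,286,10,0.125
ENDO,6,Basal anterolateral,FALSE,829,82,949,337,967,259,1096,300,10,0.023
ENDO,7,Mid-anterior,FALSE,838,114,871,323,945,187,1045,214,10,0.090
ENDO,8,Mid-anteroseptal,FALSE,817,98,903,291,900,211,1042,276,10,0.136
ENDO,9,Mid-inferoseptal,FALSE,839,107,901,332,916,224,1087,290,10,0.135
ENDO,10,Mid-inferior,FALSE,793,83,852,281,952,262,1008,251,10,0.071
ENDO,11,Mid-inferolateral,FALSE,836,98,890,305,926,260,1111,297,10,0.086
ENDO,12,Mid-anterolateral,FALSE,837,94,936,414,984,238,1110,244,10,0.204
ENDO,13,Apical anterior,FALSE,809,111,984,452,969,154,1094,314,10,0.036
ENDO,14,Apical septal,FALSE,810,133,898,450,941,205,1122,229,10,0.028
ENDO,15,Apical inferior,FALSE,835,97,863,282,902,233,1015,211,10,0.198
ENDO,16,Apical lateral,FALSE,791,143,892,295,964,181,942,180,10,0.133
EPI,1,Basal anterior,FALSE,842,90,898,358,934,189,1094,211,10,0.023
EPI,2,Basal anteroseptal,TRUE,827,157,929,326,961,174,1120,217,10,0.028
EPI,3,Basal inferoseptal,TRUE,808,133,883,325,904,234,1073,302,10,0.251
EPI,4,Basal inferior,FALSE,838,99,904,280,964,228,1053,177,10,0.028
EPI,5,Basal inferolateral,FALSE,847,113,903,322,936,177,1069,205,10,0.064
EPI,6,Basal anterolateral,FALSE,855,131,937,355,996,166,1125,218,10,0.027
EPI,7,Mid-anterior,FALSE,856,118,901,307,942,182,1106,242,10,0.068
EPI,8,Mid-anteroseptal,TRUE,824,118,912,415,911,185,1068,288,10,0.201
EPI,9,Mid-inferoseptal,TRUE,812,136,893,349,895,154,975,231,10,0.320
EPI,10,Mid-inferior,FALSE,838,88,920,335,966,229,1002,211,10,0.142
EPI,11,Mid-inferolateral,FALSE,829,114,904,341,968,201,1098,197,10,0.013
EPI,12,Mid-anterolateral,FALSE,856,107,875,296,941,165,1076,215,10,0.069
EPI,13,Apical anterior,FALSE,825,102,883,288,950,195,1075,241,10,0.042
EPI,14,Apical septal,TRUE,833,97,937,365,902,129,1078,166,10,0.008
EPI,15,Apical inferior,FALSE,829,102,838,263,933,166,1024,188,10,0.068
EPI,16,Apical lateral,FALSE,825,100,884,360,918,206,1082,266,10,0.070
EPI,17,Apex,FALSE,840,94,888,320,935,182,1054,217,10,0.069
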