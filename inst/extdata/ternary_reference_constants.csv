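system,temperature_K,k_sv_1e4,r2_sv,k_a_1e4,n_sites,r2_dl
AML,298,8.51,0.9999,1.03,0.97,0.9995
AML,310,0.30,0.9934,1.15,0.93,0.9961
ATN,298,1.32,0.9993,0.58,0.96,0.9993
ATN,310,0.90,0.9989,0.87,0.98,0.9997
FUR,298,2.80,0.9940,NA,NA,NA
FUR,310,3.93,0.9968,0.39,0.86,0.9956
QUI,298,2.23,0.9967,1.65,1.04,0.9984
QUI,310,0.96,0.9947,2.09,1.03,0.9919
VAL,298,11.10,0.9973,0.12,0.74,0.9912
VAL,310,1.19,0.9931,0.54,0.87,0.9982
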