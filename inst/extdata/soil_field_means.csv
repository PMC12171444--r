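pattern,n_level,pH_mean,pH_sd,NH4_N_mean,NH4_N_sd,NO3_N_mean,NO3_N_sd,MBN_mean,MBN_sd,MBC_mean,MBC_sd,SOC_mean,SOC_sd,TN_mean,TN_sd,AP_mean,AP_sd,AK_mean,AK_sd
NG,N0,8.36,0.04,8.26,0.75,7.41,2.06,1.67,0.46,82.5,2.45,10.7,0.21,0.51,0.13,9.87,1.06,136,18.0
NG,N1,8.27,0.03,9.44,1.22,8.22,0.72,2.24,0.19,70.0,10.1,13.5,2.78,0.52,0.02,10.1,5.96,119,16.4
NG,N2,8.16,0.03,11.3,0.75,11.1,1.72,2.90,0.90,62.0,4.93,12.4,0.89,0.60,0.23,12.7,2.18,125,17.0
NG,N3,8.15,0.04,12.4,0.94,13.9,2.44,3.53,1.20,48.3,8.03,11.8,2.42,0.65,0.15,13.1,4.33,126,12.9
OVG,N0,8.38,0.02,5.47,1.19,1.29,0.58,2.94,0.85,131,16.2,10.9,1.90,0.56,0.09,11.6,1.29,125,18.8
OVG,N1,8.37,0.04,6.75,1.02,2.96,0.61,4.27,0.58,122,8.15,14.0,1.83,0.59,0.09,10.4,2.16,123,10.0
OVG,N2,8.34,0.04,7.46,0.54,4.56,0.92,4.72,0.92,108,9.69,14.0,1.26,0.64,0.14,11.9,2.56,168,35.3
OVG,N3,8.29,0.04,8.99,0.46,5.31,0.57,5.51,0.40,110,5.02,12.8,2.01,0.63,0.03,16.9,3.68,137,12.5
VVG,N0,8.41,0.03,8.29,0.36,7.21,1.02,1.85,0.70,127,13.4,11.5,0.70,0.54,0.04,7.87,1.55,114,7.70
VVG,N1,8.30,0.02,10.4,0.59,7.96,1.24,2.40,0.67,118,12.0,13.1,1.44,0.62,0.16,12.1,5.78,115,10.2
VVG,N2,8.28,0.08,12.2,0.59,11.2,1.71,2.76,0.88,118,6.78,14.1,1.83,0.66,0.11,10.8,0.40,128,18.4
VVG,N3,8.29,0.03,13.0,1.56,12.6,1.62,3.66,1.40,111,16.8,11.6,1.69,0.62,0.10,16.5,9.00,123,16.5
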