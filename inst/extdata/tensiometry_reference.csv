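membrane,serotonin_mM,gamma_m_mN_m,gamma_m_sd,theta_deg,theta_sd
DOPC,0,1.125,0.009,31.20,0.24
DOPC,1,1.082,0.017,29.80,0.26
DOPC,5,0.982,0.024,30.89,0.33
DOPC,10,0.931,0.015,33.90,0.28
DOPC,20,0.864,0.026,40.35,0.25
DOPC,40,0.664,0.019,48.71,0.22
DOPC/SM/Chol,0,1.185,0.027,23.96,0.34
DOPC/SM/Chol,1,1.042,0.022,24.16,0.34
DOPC/SM/Chol,5,0.990,0.025,24.61,0.20
DOPC/SM/Chol,10,0.900,0.009,27.13,0.38
DOPC/SM/Chol,20,0.627,0.018,29.71,0.33
DOPC/SM/Chol,40,0.428,0.029,35.95,0.73
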