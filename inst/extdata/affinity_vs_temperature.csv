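# apparent dissociation constants of Atto-594-labelled lectins binding QD-DiMan,
# from Hill fits (n = 1) of fixed-PQR FRET-ratio titrations at three temperatures
lectin,temperature_C,kd_nM,kd_sd_nM,fmax,fmax_sd
DC-SIGN,20,1.54,0.07,3.0,0.1
DC-SIGN,25,3.00,0.04,3.00,0.01
DC-SIGN,30,5.9,1.7,3.3,0.2
DC-SIGN-C,20,1.62,0.28,3.15,0.08
DC-SIGN-C,25,1.67,0.48,2.80,0.07
DC-SIGN-C,30,1.56,0.50,2.42,0.12
DC-SIGNR,20,35,2,1.20,0.02
DC-SIGNR,25,80,6,1.31,0.04
DC-SIGNR,30,130,10,1.30,0.09
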