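species,sex,n,mass_mean_g,mass_sd_g,brightness_mean_pct,brightness_sd_pct
ungarica,F,60,1.12,0.27,18.9,3.6
ungarica,M,68,0.21,0.02,20.5,2.7
sibiricus,F,38,0.36,0.07,5.1,1.3
sibiricus,M,26,0.19,0.03,2.8,1.1
parallelus,F,120,0.22,0.04,13.2,2.7
parallelus,M,120,0.10,0.01,8.6,2.2
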