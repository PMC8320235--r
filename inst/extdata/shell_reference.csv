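cells,labeling,modality,scheme,r_nm,r_ci95,w_nm,w_ci95
U2OS,aTub + aMs-647 NHS 2deg,STORM,indirect,22.5,0.18,18.1,0.27
U2OS,aTub + aMs-647 2deg,STORM,indirect,22.5,0.22,16.9,0.34
U2OS,aTub-647 1deg,STORM,direct,20.2,0.24,10.0,0.48
U2OS,aTub + aMs-DNA 2deg,DNA-PAINT,indirect,31.8,0.14,21.6,0.19
human platelets,aTub + aMs-DNA 2deg,DNA-PAINT,indirect,29.2,0.16,21.4,0.21
human platelets,aTub-DNA 1deg,DNA-PAINT,direct,23.5,0.20,16.7,0.28
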