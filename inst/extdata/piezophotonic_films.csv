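film,thickness_um,absorbance,absorbance_is_lower_bound,mu_a_cm1,mu_a_is_lower_bound,p_max_MPa
CNT30,30,10,TRUE,7600,TRUE,0
CNT80-PDMS,80,10,TRUE,2800,TRUE,6.9
CNT30-PDMS,30,10,TRUE,7600,TRUE,7.0
CNT30-PDMS-plastic,30,10,TRUE,7600,TRUE,5.0
CNT30-PDMS-glass,30,10,TRUE,7600,TRUE,1.7
MnTPP,70,1.23,FALSE,400,FALSE,0.32
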