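class,precision,recall,f1
no_surgery,0.98,0.81,0.89
bilateral_ooph_only,0.42,0.62,0.50
hyst_and_bilateral_ooph,0.68,1.00,0.81
unilateral_ooph_only,0.94,0.74,0.83
hyst_and_unilateral_ooph,0.84,0.71,0.77
hyst_only,0.81,0.88,0.84
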