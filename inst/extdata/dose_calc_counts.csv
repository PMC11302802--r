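fm_id,n1,n2
FM36_dose_calc,8,2
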