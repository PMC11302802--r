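fm_id,O,S,D
FM36_dose_calc,4.4,8,4.7
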