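plan_id,fm_id,check_layer
282,FM36_dose_calc,1
330,FM36_dose_calc,1
366,FM36_dose_calc,1
688,FM36_dose_calc,1
798,FM36_dose_calc,1
1281,FM36_dose_calc,1
1564,FM36_dose_calc,1
1814,FM36_dose_calc,1
1911,FM36_dose_calc,2
1913,FM36_dose_calc,1
1993,FM36_dose_calc,1
2053,FM36_dose_calc,1
279,FM7_contour,1
343,FM7_contour,1
743,FM7_contour,1
849,FM7_contour,1
1305,FM7_contour,1
1450,FM7_contour,1
1559,FM7_contour,1
2322,FM7_contour,1
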