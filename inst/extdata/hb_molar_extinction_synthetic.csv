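# Synthetic coarse reconstruction of the widely used tabulated molar
# extinction coefficients of oxy- (HbO2) and deoxy-haemoglobin (Hb),
# cm^-1 / M, at 10 nm resolution over the red band 600-700 nm plus the
# 860 nm near-IR row. Values are rounded/approximate stand-ins for the
# original compilation (not reproduced here); they preserve the physical
# structure the pipeline relies on: HbO2 > Hb above the ~800 nm
# isosbestic point and Hb >> HbO2 across 600-700 nm.
wavelength_nm,hbo2_cm1_M,hb_cm1_M
600,3200.0,14677.2
610,1506.0,9443.8
620,942.0,6509.6
630,610.0,5148.8
640,442.0,4345.2
650,368.0,3750.1
660,319.6,3226.6
670,294.0,2795.1
680,277.6,2407.9
690,276.0,2052.0
700,290.0,1794.3
860,1069.6,726.4
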