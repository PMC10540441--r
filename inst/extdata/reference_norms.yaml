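# Normative reference statistics for the 17 gait parameters: mean and SD in
# native units for a reference group of 19 healthy adults (110 trials of the
# 10-m out-and-back protocol), and the z-coefficient declaring whether an
# increase in the parameter is beneficial (+1) or pathological (-1).
provenance: "healthy reference group, 19 subjects, 110 trials, 10-m out-and-back walk"
parameters:
  V:        {criterion: speed,           mean: 1.22,  sd: 0.20, z_coefficient:  1, unit: "m/s"}
  StrT:     {criterion: springiness,     mean: 1.10,  sd: 0.09, z_coefficient: -1, unit: "s"}
  UtrT:     {criterion: springiness,     mean: 2.62,  sd: 0.75, z_coefficient: -1, unit: "s"}
  LDLJ_A:   {criterion: smoothness,      mean: -8.07, sd: 0.35, z_coefficient:  1, unit: "-"}
  SPARC_G:  {criterion: smoothness,      mean: -5.37, sd: 0.84, z_coefficient: -1, unit: "-"}
  CV_StrT:  {criterion: steadiness,      mean: 2.34,  sd: 0.97, z_coefficient: -1, unit: "%"}
  CV_dstT:  {criterion: steadiness,      mean: 5.63,  sd: 2.07, z_coefficient: -1, unit: "%"}
  P1_aCC:   {criterion: steadiness,      mean: 0.82,  sd: 0.10, z_coefficient:  1, unit: "-"}
  P2_aCC:   {criterion: steadiness,      mean: 0.82,  sd: 0.10, z_coefficient:  1, unit: "-"}
  SteL:     {criterion: sturdiness,      mean: 0.68,  sd: 0.08, z_coefficient:  1, unit: "m"}
  RMS_aML:  {criterion: stability,       mean: 1.28,  sd: 0.33, z_coefficient: -1, unit: "m/s^2"}
  iHR_aAP:  {criterion: symmetry,        mean: 95.48, sd: 2.13, z_coefficient:  1, unit: "%"}
  iHR_aCC:  {criterion: symmetry,        mean: 94.88, sd: 3.10, z_coefficient:  1, unit: "%"}
  iHR_aML:  {criterion: symmetry,        mean: 86.77, sd: 6.32, z_coefficient:  1, unit: "%"}
  P1P2_aCC: {criterion: symmetry,        mean: 0.96,  sd: 0.04, z_coefficient:  1, unit: "-"}
  swTr:     {criterion: symmetry,        mean: 0.96,  sd: 0.03, z_coefficient:  1, unit: "-"}
  dstT:     {criterion: synchronization, mean: 23.34, sd: 3.50, z_coefficient: -1, unit: "%"}
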