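# Electron CSDA range-energy table, unit-density liquid water.
# Columns: energy_MeV, range_um.
# Best-effort transcription (rounded) of tabulated CSDA ranges for
# liquid water from standard stopping-power compilations; used by
# the "tabulated" electron range-energy relation (the alternative
# to the default Cole-type empirical power law).  Interpolated in
# log-log space by the transport module.
energy_MeV,range_um
0.001,0.05
0.002,0.15
0.005,0.80
0.010,2.52
0.015,5.10
0.020,8.57
0.030,17.6
0.040,29.1
0.050,43.2
0.070,78.0
0.100,143.1
0.150,283.0
0.200,449.0
0.300,842.0
0.500,1766
0.700,2790
1.000,4367
2.000,9790
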