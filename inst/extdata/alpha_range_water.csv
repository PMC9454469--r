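# Alpha-particle range-energy table, unit-density liquid water.
# Columns: energy_MeV, range_um (CSDA range, straight track).
# Generated from the classic Geiger / Bragg-Kleeman empirical rule
# (air range 0.318*E^1.5 cm scaled to unit-density water), i.e.
# range_um = 3.21 * E_MeV^1.5.  Agrees with ICRU-49-class CSDA
# ranges to within a few percent over the 4-9 MeV therapy window.
# Interpolated in log-log space by the transport module.
energy_MeV,range_um
0.25,0.401
0.5,1.135
1.0,3.210
1.5,5.897
2.0,9.079
2.5,12.69
3.0,16.68
3.5,21.02
4.0,25.68
4.5,30.64
5.0,35.89
5.5,41.40
6.0,47.18
6.5,53.18
7.0,59.45
7.5,65.93
8.0,72.63
8.5,79.54
9.0,86.67
9.5,93.99
10.0,101.51
11.0,117.11
12.0,133.44
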