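# Condensed per-decay emission tables.
# Columns: nuclide, icode (radiation-type code), yield_per_decay
# (emissions per nuclear transition of that nuclide), energy_MeV
# (mean energy for beta average-energy lines, discrete energy
# otherwise).
# Provenance: best-effort condensed transcription of standard
# decay-scheme compilations (MIRD monograph / ENSDF lineage).  Beta
# decays are represented by their average-energy line; low-yield
# lines are merged or dropped.  Gamma and X-ray lines are retained
# for completeness but are excluded from all dose computation
# (photons are ignored by the dosimetry engine).
nuclide,icode,yield_per_decay,energy_MeV
Bi-213,alpha,0.0216,5.869
Bi-213,beta_minus,0.9780,0.4250
Bi-213,gamma,0.2610,0.4405
Bi-213,ic_electron,0.0170,0.3520
Bi-213,auger,0.0230,0.0080
Po-213,alpha,1.0000,8.376
Tl-209,beta_minus,1.0000,0.6590
Tl-209,gamma,0.9970,1.5670
Tl-209,gamma,0.9690,0.4650
Pb-209,beta_minus,1.0000,0.1980
In-111,gamma,0.9070,0.1713
In-111,gamma,0.9410,0.2454
In-111,ic_electron,0.0820,0.1446
In-111,ic_electron,0.0500,0.2186
In-111,ic_electron,0.0100,0.1674
In-111,ic_electron,0.0100,0.2414
In-111,auger,0.1560,0.0194
In-111,auger,1.0200,0.0026
In-111,xray,0.6800,0.0230
At-211,alpha,0.4180,5.870
At-211,xray,0.5800,0.0790
Po-211,alpha,0.9900,7.450
Ra-223,alpha,1.0000,5.667
Ra-223,gamma,0.1390,0.2699
Ra-223,ic_electron,0.1500,0.2540
Ra-223,auger,0.7500,0.0100
Rn-219,alpha,1.0000,6.819
Rn-219,gamma,0.1080,0.2712
Po-215,alpha,1.0000,7.386
Pb-211,beta_minus,1.0000,0.4470
Pb-211,gamma,0.0378,0.8319
Bi-211,alpha,0.9972,6.623
Bi-211,gamma,0.1270,0.3510
Tl-207,beta_minus,1.0000,0.4930
Ac-225,alpha,1.0000,5.830
Ac-225,gamma,0.0110,0.0999
Fr-221,alpha,1.0000,6.341
Fr-221,gamma,0.1140,0.2183
At-217,alpha,1.0000,7.067
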