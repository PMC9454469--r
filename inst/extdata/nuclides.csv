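# Physical half-lives of the packaged radionuclides.
# Values are best-effort transcriptions of standard decay-scheme
# compilations (MIRD monograph / ENSDF lineage), rounded; they are
# configuration data, not asserted ground truth.  Nuclides marked
# stable_or_terminal have no emissions in the packaged tables and
# terminate chain expansion (Bi-207 is quasi-stable on therapy
# timescales, T1/2 ~ 32 y).
name,half_life_s,terminal
Bi-213,2736.6,0
Po-213,4.2e-6,0
Tl-209,129.7,0
Pb-209,11642,0
Bi-209,Inf,1
In-111,242332,0
At-211,25970,0
Po-211,0.516,0
Bi-207,1.02e9,1
Ra-223,987552,0
Rn-219,3.96,0
Po-215,1.781e-3,0
Pb-211,2166,0
Bi-211,128.4,0
Tl-207,286.2,0
Pb-207,Inf,1
Ac-225,857088,0
Fr-221,288,0
At-217,0.0323,0
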