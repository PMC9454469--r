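# Decay-chain branching fractions (parent -> daughter, fraction of
# parent transitions).  Best-effort transcription of standard decay
# schemes; daughters are treated as in secular equilibrium with the
# parent when a chain is expanded.
parent,daughter,fraction
Bi-213,Po-213,0.9780
Bi-213,Tl-209,0.0220
Po-213,Pb-209,1.0
Tl-209,Pb-209,1.0
Pb-209,Bi-209,1.0
At-211,Po-211,0.582
At-211,Bi-207,0.418
Po-211,Pb-207,1.0
Ra-223,Rn-219,1.0
Rn-219,Po-215,1.0
Po-215,Pb-211,1.0
Pb-211,Bi-211,1.0
Bi-211,Tl-207,0.9972
Tl-207,Pb-207,1.0
Ac-225,Fr-221,1.0
Fr-221,At-217,1.0
At-217,Bi-213,1.0
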