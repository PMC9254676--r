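location_underpass,prey,n,expected,observed,signif
Port-U1,Bandicoots/pademelons,245,0.280,0.074,0.001
Port-U1,Wallabies,517,0.179,0.077,0.001
Port-U2,Pademelons/bandicoots,219,0.157,0.081,0.001
Port-U2,Wallabies,222,0.171,0.077,0.001
Port-U3,Wallabies,358,0.303,0.115,0.001
Grafton-U2,Bettongs/bandicoots,142,0.179,0.021,0.001
Grafton-U2,Wallabies,67,0.257,0.015,0.001
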