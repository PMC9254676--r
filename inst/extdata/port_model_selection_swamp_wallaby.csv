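model,AICc,K
p(Patchy),1097.30,6
p(Underpass),1205.85,3
p(null),1257.60,2
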