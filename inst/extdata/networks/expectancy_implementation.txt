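# Illustrative placeholder node list (Destrieux-style labels).
G_precentral L
G_front_sup R
G_front_sup L
G_cingul-Post-dorsal L
G_parietal_sup L
S_intrapariet_and_P_trans R
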