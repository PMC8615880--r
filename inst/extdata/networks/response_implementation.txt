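# Illustrative placeholder node list (Destrieux-style labels).
# Replace with the region set of your own study.
G_precentral L
G_precentral R
G_postcentral L
G_front_sup R
G_parietal_sup L
G_pariet_inf-Supramar L
S_central L
G_front_middle R
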