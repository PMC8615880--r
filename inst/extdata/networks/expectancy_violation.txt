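# Illustrative placeholder node list (Destrieux-style labels).
G_front_sup R
G_front_middle R
G_postcentral L
G_pariet_inf-Supramar L
G_temp_sup-Lateral R
S_central L
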