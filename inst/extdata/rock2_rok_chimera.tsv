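# Splice points of the human ROCK2 / Drosophila Rok coiled-coil swap
# chimera (recorded as a fixture; no splice-point optimization is done).
segment	source	start	end
kinase	human_ROCK2	1	413
coiled_coil	drosophila_Rok	418	1133
regulatory	human_ROCK2	1142	1379
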