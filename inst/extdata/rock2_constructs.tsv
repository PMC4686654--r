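# Published human ROCK2 coiled-coil deletion series (residue endpoints,
# 1-based inclusive). Derived columns are recomputed by the ruler at load.
name	del_start	del_end
d2nm	440	453
d5nm	440	471
d10nm	440	509
d20nm	440	575
d30nm	440	645
d60nm	440	849
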