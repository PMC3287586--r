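word	polarity
activates	activation
activate	activation
activated	activation
induces	activation
induce	activation
induced	activation
stimulates	activation
stimulate	activation
stimulated	activation
upregulates	activation
upregulate	activation
upregulated	activation
up-regulates	activation
enhances	activation
enhance	activation
enhanced	activation
promotes	activation
promote	activation
promoted	activation
transactivates	activation
triggers	activation
increases	activation
augments	activation
potentiates	activation
maintains	activation
represses	repression
repress	repression
repressed	repression
inhibits	repression
inhibit	repression
inhibited	repression
downregulates	repression
downregulate	repression
downregulated	repression
down-regulates	repression
suppresses	repression
suppress	repression
suppressed	repression
silences	repression
silenced	repression
antagonizes	repression
blocks	repression
blocked	repression
abolishes	repression
decreases	repression
attenuates	repression
destabilizes	repression
prevents	repression
binds	neutral
bind	neutral
bound	neutral
interacts	neutral
interact	neutral
associates	neutral
associate	neutral
phosphorylates	neutral
phosphorylate	neutral
phosphorylated	neutral
dephosphorylates	neutral
ubiquitinates	neutral
methylates	neutral
acetylates	neutral
regulates	neutral
regulate	neutral
regulated	neutral
targets	neutral
recruits	neutral
sequesters	neutral
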