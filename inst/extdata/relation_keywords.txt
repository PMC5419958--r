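bind
binds
binding
bound
activate
activates
activated
activation
inhibit
inhibits
inhibited
inhibition
phosphorylate
phosphorylates
phosphorylated
phosphorylation
interact
interacts
interaction
regulate
regulates
regulated
regulation
express
expresses
expressed
expression
induce
induces
induced
induction
suppress
suppresses
suppressed
encode
encodes
encoded
mediate
mediates
mediated
associate
associates
associated
stimulate
stimulates
stimulated
repress
represses
repressed
transactivate
transactivates
cleave
cleaves
cleaved
recruit
recruits
recruited
dimerize
dimerizes
ubiquitinate
ubiquitinates
acetylate
acetylates
methylate
methylates
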