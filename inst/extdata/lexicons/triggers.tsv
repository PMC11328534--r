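surface	polarity	strategy_tag
allergie	positive	keyword
bijwerking	positive	keyword
overgevoeligheid	positive	keyword
intolerantie	positive	keyword
gestaakt	positive	keyword
wegens	positive	preposition
door	positive	preposition
na	positive	preposition
medicatie gerelateerd	positive	phrase
voorgeschiedenis	negative	keyword
familieanamnese	negative	keyword
# "dd" (Dutch dosing shorthand, e.g. "2 dd 1") drowns the output in false
# positives (PPV < 0.1%); kept here disabled as a cautionary example.
# dd	positive	keyword
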