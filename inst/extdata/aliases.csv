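# ASCII aliases accepted on input and normalised to the canonical
# UTF-8 symbols of the feature tables.  Tie-bar characters on the
# affricates are stripped in code before alias resolution.
ascii,ipa
E,ε
O,ɔ
@,ə
N,ŋ
S,ʃ
Z,ʒ
tS,tʃ
dZ,dʒ
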