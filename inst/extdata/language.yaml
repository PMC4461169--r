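# Miniature Hungarian-based target language: 4 container nouns crossed with
# 3 locative cases, each case having a [-back]/[+back] vowel-harmony
# alternation.  Stems and suffixes are written in the ASCII alias
# transcription (E = /ε/, O = /ɔ/, S = /ʃ/, tS = /tʃ/).
#
# The inessive pair (-bEn / -bOn) is as described for the study language.
# The adessive and superessive surface forms are a RECONSTRUCTION following
# standard Hungarian two-way harmony pairs (adessive -nál/-nél, superessive
# -on/-en), transcribed into the study's phoneme set; the exact forms used
# in the original figure are not recoverable from its text.
nouns:
  - stem: "SyvEg"
    harmony: "front"
    gloss: "hat"
    image_id: "img_hat"
  - stem: "sEmEtES"
    harmony: "front"
    gloss: "bin"
    image_id: "img_bin"
  - stem: "dObOz"
    harmony: "back"
    gloss: "box"
    image_id: "img_box"
  - stem: "bOgratS"
    harmony: "back"
    gloss: "cauldron"
    image_id: "img_cauldron"
cases:
  - name: "inessive"
    gloss: "in"
    front_suffix: "bEn"
    back_suffix: "bOn"
  - name: "adessive"
    gloss: "by"
    front_suffix: "nEl"
    back_suffix: "nal"
  - name: "superessive"
    gloss: "on"
    front_suffix: "En"
    back_suffix: "On"
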