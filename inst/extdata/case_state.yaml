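# Worked-example case state: apparent de novo mutation, paternity confirmed,
# parental blood deep sequencing negative, paternal origin, semen available.
inheritance_mode: AR
apparent_de_novo: true
paternity_confirmed: true
parental_blood_tngs: negative
origin: paternal
semen_available: true
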