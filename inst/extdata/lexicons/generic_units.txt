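# generic health-care unit terms: not identifiable on their own
Geriatriken
Akuten
Medicinkliniken
Kirurgen
Ortopeden
Röntgen
Vårdcentralen
Intensiven
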