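# abbreviations kept whole by the tokenizer (trailing period included)
univ.
sjukh.
avd.
dr.
mott.
med.
kir.
ort.
pat.
ssk.
t.ex.
bl.a.
p.g.a.
enl.
kl.
st.
nr.
tel.
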