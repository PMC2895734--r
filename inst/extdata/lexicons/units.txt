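Karolinska Univ. Sjukh, Huddinge
Karolinska/Huddinge
Avd. 11 på Karolinska
Södersjukhuset avd. 23
S:t Görans sjukhus
Danderyds sjukhus, akutmott.
Vårdcentralen Tallbacken
Huddinge vårdcentral
Capio S:t Göran ortopedmott.
Astrid Lindgrens barnsjukhus
Geriatrikmott. Danderyds sjukhus
Norrtälje sjukhus med. avd. 2
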