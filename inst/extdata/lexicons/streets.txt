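Storgatan 1, 114 44 Stockholm
Vasavägen 12, 171 64 Solna
Björkvägen 3
Sjukhusbacken 10, 118 83 Stockholm
Kyrkogatan 7, 141 35 Huddinge
Aspstigen 22
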