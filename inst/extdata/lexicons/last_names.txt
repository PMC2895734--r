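Svensson
Lindqvist
Johansson
Bergström
Nilsson
Åkesson
Karlsson
Öberg
Andersson
Lundgren
Eriksson
Holmberg
Pettersson
Sjögren
Larsson
Wikström
Dahlberg
Nyström
Forsberg
Hellström
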