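Anna
Erik
Maria
Lars
Karin
Johan
Eva
Anders
Sara
Per
Lena
Mikael
Ingrid
Olof
Birgitta
Nils
Astrid
Gunnar
Elsa
Henrik
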