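# synthetic hexamer set (fixture; not a published screen)
>ese_ga_rich
GAAGAA
GUAGAA
CAAAAA
GGAGAG
GAAGAU
GAACAA
GACGAG
GAACAC
GAAAAA
>ese_ca_rich
ACAGCA
AGAGCU
AUAGCG
ACAGGA
AAAGAA
ACAACA
UCAGUA
ACGGCA
ACAGUA
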