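# synthetic hexamer set (fixture; not a published screen)
>ess_uag
UAGGGU
UAGGCU
ACGGGU
UAGUAU
UCGGGU
UAGGAU
UAAAGU
AAGGGC
CAGGGU
>ess_ucua
UCUAGU
CCUAAU
GCUAGU
UCCAGU
ACAAGU
UCGAGU
CCAAGU
CCUAGG
UCUGGU
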