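# synthetic hexamer set (fixture; not a published screen)
>rbp_ex_uaggua
UAGGUA
UCGGCA
UGGAUA
CAGGUA
UACAUA
GGGGUA
UAUGCA
GCGGUA
UAGGUC
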