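# synthetic hexamer set (fixture; not a published screen)
>iss_cu_rich
UCUCUC
ACUCUC
UAUCUC
UCUUUC
UCUCAC
CCUCUC
UCUCUG
UCGCUC
GCUCUU
>iss_ccuc
CCUCCU
CCUCGU
UGUCCU
GGUCCU
GCGCCU
CCUCCG
CCUACU
UCUCCU
CCCCCU
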