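# synthetic hexamer set (fixture; not a published screen)
>ise_g_run
GGGGUG
GCGUUG
CAGGUG
GUGGUG
GGGGUC
GAGGUG
GGGGAC
GGGGGG
GGGAUC
>ise_ugca
UGCAUG
GGCAUG
UGCGUA
CGCAUG
UGCAUU
AGCAUG
AGCAUU
UGAAUG
UGCAGG
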