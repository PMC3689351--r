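sample_id	locality	country	species
AA0001	AA	C01	forest
AA0002	AA	C01	forest
AA0003	AA	C01	forest
AA0004	AA	C01	forest
AA0005	AA	C01	forest
AA0006	AA	C01	forest
AA0007	AA	C01	forest
AA0008	AA	C01	forest
AB0001	AB	C01	forest
AB0002	AB	C01	forest
AB0003	AB	C01	forest
AB0004	AB	C01	forest
AB0005	AB	C01	forest
AB0006	AB	C01	forest
AB0007	AB	C01	forest
AB0008	AB	C01	forest
AC0001	AC	C02	savanna
AC0002	AC	C02	savanna
AC0003	AC	C02	savanna
AC0004	AC	C02	savanna
AC0005	AC	C02	savanna
AC0006	AC	C02	savanna
AC0007	AC	C02	savanna
AC0008	AC	C02	savanna
AD0001	AD	C02	savanna
AD0002	AD	C02	savanna
AD0003	AD	C02	savanna
AD0004	AD	C02	savanna
AD0005	AD	C02	savanna
AD0006	AD	C02	savanna
AD0007	AD	C02	savanna
AD0008	AD	C02	savanna
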