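region,year,population_thousands
IN,2016,1310000
IN,2017,1310000
IN,2018,1310000
IN,2019,1310000
KL,2016,34900
KL,2017,34900
KL,2018,34900
KL,2019,34900
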