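# Compact ENVO term dictionary for exact-match environment tagging.
label	envo_id
soil	ENVO:00001998
forest soil	ENVO:00002261
agricultural soil	ENVO:00002259
grassland soil	ENVO:00005750
peat soil	ENVO:00005774
tundra soil	ENVO:00005753
forest	ENVO:01000174
temperate forest	ENVO:01000189
tropical forest	ENVO:01000185
boreal forest	ENVO:01000250
woodland	ENVO:00000109
grassland	ENVO:01000177
tundra	ENVO:01000180
shrubland	ENVO:01000176
desert	ENVO:01000179
wetland	ENVO:00000043
peatland	ENVO:00000044
bog	ENVO:01000534
marsh	ENVO:00000035
mangrove	ENVO:01000181
freshwater	ENVO:00002011
sediment	ENVO:00002007
marine sediment	ENVO:03000033
seawater	ENVO:00002149
rhizosphere	ENVO:00005801
leaf litter	ENVO:01000628
decaying wood	ENVO:01000902
dune	ENVO:00000170
alpine meadow	ENVO:01001505
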