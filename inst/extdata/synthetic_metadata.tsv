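genome_id	environment	name
G01	HTV	vent strain 1
G02	HTV	vent strain 2
G03	nonHTV	reference strain 1
G04	nonHTV	reference strain 2
G05	nonHTV	reference strain 3
G06	nonHTV	reference strain 4
G07	nonHTV	reference strain 5
G08	nonHTV	reference strain 6
G09	nonHTV	reference strain 7
G10	nonHTV	reference strain 8
G11	nonHTV	reference strain 9
G12	nonHTV	reference strain 10
G13	nonHTV	reference strain 11
G14	nonHTV	reference strain 12
G15	nonHTV	reference strain 13
G16	nonHTV	reference strain 14
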