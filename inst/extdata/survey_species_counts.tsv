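species	n_eves	n_duplication_events
Armadillidium_nasatum	69	0
Daphnia_pulex	22	1
Daphnia_pulicaria	74	3
Eurytemora_affinis	10	1
Hyalella_azteca	22	1
Lepeophtheirus_salmonis	13	1
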