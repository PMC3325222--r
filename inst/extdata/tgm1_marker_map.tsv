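marker	kind	distance_mb
D14S275	microsatellite	1.98
D14S742	microsatellite	2.52
D14S72	microsatellite	3.32
D14S1043	microsatellite	3.34
D14S1042	microsatellite	4.54
D14S1060	microsatellite	8.7
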