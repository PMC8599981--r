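feature	group	event_class	cnv_set	mean_case	mean_control
n_events	ALL	DelDup	all	4073	4079
n_events	ALL	Del	all	2249	2261
n_events	ALL	Dup	all	1823	1818
n_events	NHW	DelDup	all	3991	3972
n_events	NHW	Del	all	2129	2127
n_events	NHW	Dup	all	1861	1845
n_events	NHW	DelDup	rare	45.33	38.81
n_events	NHW	Del	rare	34.1	29.01
n_events	NHW	Dup	rare	11.23	9.8
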