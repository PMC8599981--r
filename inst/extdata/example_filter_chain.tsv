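step	group	status	count
initial	AA	case	472
initial	AA	control	521
initial	AA	unknown	44
initial	Hispanic	case	826
initial	Hispanic	control	746
initial	Hispanic	unknown	40
initial	NHW	case	910
initial	NHW	control	820
initial	NHW	unknown	393
initial	Other	case	5
initial	Other	control	4
initial	Other	unknown	7
replicate_removal	AA	case	467
replicate_removal	AA	control	521
replicate_removal	AA	unknown	44
replicate_removal	Hispanic	case	810
replicate_removal	Hispanic	control	733
replicate_removal	Hispanic	unknown	40
replicate_removal	NHW	case	910
replicate_removal	NHW	control	815
replicate_removal	NHW	unknown	393
replicate_removal	Other	case	5
replicate_removal	Other	control	4
replicate_removal	Other	unknown	7
unknown_status_removal	AA	case	467
unknown_status_removal	AA	control	521
unknown_status_removal	Hispanic	case	810
unknown_status_removal	Hispanic	control	733
unknown_status_removal	NHW	case	910
unknown_status_removal	NHW	control	815
unknown_status_removal	Other	case	5
unknown_status_removal	Other	control	4
uneven_coverage_removal	AA	case	466
uneven_coverage_removal	AA	control	521
uneven_coverage_removal	Hispanic	case	808
uneven_coverage_removal	Hispanic	control	731
uneven_coverage_removal	NHW	case	902
uneven_coverage_removal	NHW	control	813
uneven_coverage_removal	Other	case	5
uneven_coverage_removal	Other	control	4
relatedness_removal	AA	case	457
relatedness_removal	AA	control	521
relatedness_removal	Hispanic	case	520
relatedness_removal	Hispanic	control	727
relatedness_removal	NHW	case	755
relatedness_removal	NHW	control	811
relatedness_removal	Other	case	5
relatedness_removal	Other	control	4
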