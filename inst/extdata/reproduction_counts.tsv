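#condition	n_reproduced	n_validated_pos	raw_candidates	accepted
glioblastoma	3947	4141	6856440	105564
lymphoblastoid	20504	22688	58666976	3076908
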