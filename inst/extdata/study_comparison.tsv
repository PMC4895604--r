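#condition	reads	bases	raw_rdds	accepted_rdds
glioblastoma	115132348	13815881760	6856440	105564
lymphoblastoid	583640030	101787059720	58666976	3076908
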