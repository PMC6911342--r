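name	forward	reverse
pri_mir319a_pairA_synthetic	AACTGCAGGCCACGTGTTTT	TCTTTTGATAGAGATCTCGG
pri_mir319a_pairB_synthetic	GCGGACAATTAAGATCGCGA	CGATAATGCTTCTTAAATAA
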