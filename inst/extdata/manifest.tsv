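id	stream	path	label	fold
seg001	d0	codes/seg001_d0.tsv	cooking	0
seg001	d+30	codes/seg001_dp30.tsv	cooking	0
seg002	d0	codes/seg002_d0.tsv	absence	1
seg002	d+30	codes/seg002_dp30.tsv	absence	1
seg003	d0	codes/seg003_d0.tsv	eating	0
seg003	d+30	codes/seg003_dp30.tsv	eating	0
seg004	d0	codes/seg004_d0.tsv	cooking	1
seg004	d+30	codes/seg004_dp30.tsv	cooking	1
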