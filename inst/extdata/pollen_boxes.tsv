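# Editable panel of candidate pollen/anther cis-elements screened by
# pollen_box_screen(). POLLEN1LELAT52 is the literature-anchored entry;
# replace the CANDIDATE_BOX rows with your own panel.
name	consensus
POLLEN1LELAT52	AGAAA
GTGANTG10	GTGA
POLLEN2LELAT52	TCCACCATA
CANDIDATE_BOX4	TGTGGT
CANDIDATE_BOX5	CACGTG
CANDIDATE_BOX6	ACGTCA
CANDIDATE_BOX7	TCTCGTAT
CANDIDATE_BOX8	AACCGG
CANDIDATE_BOX9	GGTTTA
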