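# Published full-length coordinates of the signal peptide and propeptide
# segments of the three zebrafish collagen I chains, determined in the
# source study by cleavage-site sequence alignment with human COL1A1/
# COL1A2. Note: the COL1A1b C-propeptide end is printed as 1447 although
# the chain is described as 1449 aa long; transcribed as printed.
chain_id	segment	start	end
COL1A1a	signal_peptide	1	22
COL1A1a	n_propeptide	23	146
COL1A1a	c_propeptide	1202	1447
COL1A1b	signal_peptide	1	22
COL1A1b	n_propeptide	23	150
COL1A1b	c_propeptide	1204	1447
COL1A2	signal_peptide	1	22
COL1A2	n_propeptide	23	68
COL1A2	c_propeptide	1109	1352
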