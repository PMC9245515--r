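# Conservation status of the 24 COL1A1a 3-hydroxyproline sites of the
# zebrafish heart ECM catalog: "conserved" sites were also identified in
# re-analyzed human and mouse heart COL1A1, "novel" sites are zebrafish-
# specific. Positions are full-length zebrafish COL1A1a coordinates; the
# reference_position column is the matched human/mouse COL1A1 catalog
# position expressed on the same coordinate frame (synthetic identity
# mapping, shipped as a stand-in for the unpublished human/mouse
# coordinates).
position	status	reference_position
176	conserved	176
188	novel	NA
317	novel	NA
401	novel	NA
443	novel	NA
446	novel	NA
551	conserved	551
623	novel	NA
707	novel	NA
755	conserved	755
800	conserved	800
854	novel	NA
869	conserved	869
878	novel	NA
881	conserved	881
911	conserved	911
980	novel	NA
992	novel	NA
1034	novel	NA
1103	conserved	1103
1106	conserved	1106
1148	conserved	1148
1166	novel	NA
1169	novel	NA
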