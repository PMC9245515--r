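# The 23 collagen chains of the published zebrafish heart ECM PTM site
# catalog, in table order. COL2A1b is listed in the source table with no
# site entries.
chain_id
COL1A1a
COL1A1b
COL1A2
COL4A1
COL5A1
COL5A2a
COL6A1
COL6A3
COL6A2
COL11A1a
COL4A2
COL4A5
COL6A4a
COL2A1a
COL2A1b
COL16A1
COL11A1b
COL5A2b
COL11A2
COL7A1
COL5A3b
COL22A1
COL17A1a
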