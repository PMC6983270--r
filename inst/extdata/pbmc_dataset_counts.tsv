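dataset	n_barcodes	n_doublets
cell_hashing	8402	1869
demuxlet_filtered	6525	1426
demuxlet_full	14619	1565
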