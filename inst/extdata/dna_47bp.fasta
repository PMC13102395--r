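>dsDNA_47bp strand 1 (5'->3')
GGCGACGTGATCACCAGATGATGCTAGATGCTTTCCGAAGAGAGAGC
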