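# default concatemer library architecture
target_len = 120
spacer5_len = 33
spacer3_len = 34
# adapter = <sequence or FASTA path>; bundled default used when absent
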