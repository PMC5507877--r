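>concatseq_adapter_default 30 bp, GC 0.40
GTTTTCGTAGGTGAAAACGCCCACATATTA
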