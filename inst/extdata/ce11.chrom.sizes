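chrI	15072434
chrII	15279421
chrIII	13783801
chrIV	17493829
chrV	20924180
chrX	17718942
chrM	13794
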