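>seq1
AAAAA
>seq2
AAAAR
>seq3
AACCC
>seq4
ACC-C
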