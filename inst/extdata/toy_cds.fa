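>cds1 toy
ATGTTTACCGGATAA
>cds2 toy
ATGGCTAAACTGTGTTAG
>bad_no_atg
TTGAAATAA
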