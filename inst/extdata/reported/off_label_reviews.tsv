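run	off_label	reviewed
1	7	100
2	10	100
3	3	100
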