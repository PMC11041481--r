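unique_answers	n
1	28224
2	6804
3	1530
>=4	954
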