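category	n
one_drug_no_reason	46278
one_reason_categories	28224
multi_reason_categories	22437
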