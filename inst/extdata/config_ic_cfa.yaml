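# independent-clusters CFA on the bundled mini-IPIP layout
items: minipip
model: ic_cfa
constraints: none
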