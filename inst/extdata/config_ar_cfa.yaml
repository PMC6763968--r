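# AR-CFA with adjacent + construct-specific AR structure on the mini-IPIP
items: minipip
model: ar_cfa
topology: adjacent_plus_construct
constraints: none
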