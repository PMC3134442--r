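category	printed_count	printed_percent
Mitochondrion	150	27.7
Nucleus	69	12.8
Cell wall	22	4.1
Vacuole	24	4.4
Unknown cellular component	179	33.1
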