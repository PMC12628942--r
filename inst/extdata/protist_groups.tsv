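genus	group
Cercomonas	consumer
Euglypha	consumer
Trinema	consumer
Rhogostoma	consumer
Heteromita	consumer
Naegleria	consumer
Acanthamoeba	consumer
Vampyrella	consumer
Colpoda	consumer
Chlamydomonas	phototroph
Chlorella	phototroph
Coccomyxa	phototroph
Klebsormidium	phototroph
Navicula	phototroph
Hantzschia	phototroph
Phytophthora	pathotroph
Pythium	pathotroph
Aphanomyces	pathotroph
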