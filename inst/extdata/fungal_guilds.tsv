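genus	guild
Alternaria	Pathotroph-Saprotroph-Symbiotroph
Fusarium	Pathotroph-Saprotroph
Ophiobolus	Pathotroph
Botryosphaeria	Pathotroph-Saprotroph
Curvularia	Pathotroph-Saprotroph
Aspergillus	Saprotroph
Penicillium	Saprotroph
Chaetomium	Saprotroph
Idriella	Saprotroph
Preussia	Saprotroph
Mortierella	Saprotroph-Symbiotroph
Coniochaeta	Saprotroph-Pathotroph
Glomus	Symbiotroph
Rhizophagus	Symbiotroph
Tuber	Symbiotroph
Serendipita	Symbiotroph-Saprotroph
Cladosporium	Pathotroph-Saprotroph-Symbiotroph
Phoma	Pathotroph-Saprotroph
Talaromyces	Saprotroph
Acremonium	Saprotroph-Pathotroph
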