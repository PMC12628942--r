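genus	family	mean_rrn
Bacillus	Bacillaceae	9.6
Streptomyces	Streptomycetaceae	6.3
Paenibacillus	Paenibacillaceae	7.8
Clostridium	Clostridiaceae	8.9
Vibrio	Vibrionaceae	9.1
Pseudomonas	Pseudomonadaceae	4.9
Arthrobacter	Micrococcaceae	4.4
Mycobacterium	Mycobacteriaceae	1.6
Bradyrhizobium	Bradyrhizobiaceae	1.3
Nitrospira	Nitrospiraceae	1.2
Rubrobacter	Rubrobacteraceae	2.0
Solirubrobacter	Solirubrobacteraceae	1.5
Gaiella	Gaiellaceae	1.0
Balneimonas	Methylobacteriaceae	3.4
Pseudonocardia	Pseudonocardiaceae	2.8
Sphingomonas	Sphingomonadaceae	2.1
Geodermatophilus	Geodermatophilaceae	2.4
Ktedonobacter	Ktedonobacteraceae	2.2
Conexibacter	Conexibacteraceae	1.8
Microvirga	Methylobacteriaceae	3.1
Bosea	Bradyrhizobiaceae	1.9
Azospirillum	Azospirillaceae	5.5
Micromonospora	Micromonosporaceae	3.0
Acidobacterium	Acidobacteriaceae	1.1
Flavobacterium	Flavobacteriaceae	5.2
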