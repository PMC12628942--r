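Abridged functional-guild lookup tables (synthetic stand-ins).

These small tables carry plausible genera with approximate literature-style
values so that the annotation code paths can run self-contained:

  rrn_copies.tsv     genus/family -> mean rRNA operon (rrn) copy number;
                     >= 5 copies classifies a bacterium as copiotroph,
                     < 5 as oligotroph.
  fungal_guilds.tsv  genus -> multi-mode trophic guild string; the
                     first-listed mode is taken as the dominant role.
  protist_groups.tsv genus -> feeding-habit group (consumer, phototroph,
                     pathotroph).

They are NOT complete reference databases. For real analyses supply full
rrnDB-derived, FUNGuild-derived and feeding-habit tables in the same format
via the lookup arguments of classify_functional_groups().
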