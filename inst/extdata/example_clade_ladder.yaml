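# Ordered oldest -> youngest; genes at or before the boundary are "ancient"
clades:
  - Eukaryota
  - Opisthokonta
  - Metazoa
  - Eumetazoa
  - Bilateria
  - Deuterostomia
  - Chordata
  - Euteleostomi
  - Amniota
  - species_specific
ancient_boundary: Eukaryota
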