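version: seed-1
policy:
  mode: window
  window_tokens: 3
  bidirectional: yes
search_terms:
- surface: otitis media
  case_sensitive: no
  note: attested in source running text
- surface: OM
  case_sensitive: yes
  note: attested abbreviation, otitis media
- surface: AOM
  case_sensitive: yes
  note: acute otitis media abbreviation
- surface: ROM
  case_sensitive: yes
  note: attested; right otitis media, ambiguous with range of movement
- surface: LOM
  case_sensitive: yes
  note: synthetic completion; left otitis media
- surface: BOM
  case_sensitive: yes
  note: synthetic completion; bilateral otitis media
- surface: T/M
  case_sensitive: yes
  note: attested tympanic-membrane variant
- surface: t/m
  case_sensitive: yes
  note: attested tympanic-membrane variant
- surface: tm
  case_sensitive: yes
  note: attested tympanic-membrane variant
- surface: TM
  case_sensitive: yes
  note: attested tympanic-membrane variant
- surface: TMs
  case_sensitive: yes
  note: synthetic completion; plural tympanic-membrane form
- surface: glue ear
  case_sensitive: no
  note: synthetic completion; otitis media with effusion, lay term
- surface: ear infection
  case_sensitive: no
  note: synthetic completion
- surface: middle ear
  case_sensitive: no
  note: synthetic completion
- surface: eardrum
  case_sensitive: no
  note: synthetic completion
exclusion_words:
- surface: normal
  case_sensitive: no
- surface: clear
  case_sensitive: no
- surface: intact
  case_sensitive: no
- surface: pearly
  case_sensitive: no
- surface: NAD
  case_sensitive: yes
- surface: healthy
  case_sensitive: no
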