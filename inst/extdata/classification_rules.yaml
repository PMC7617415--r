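# Editable codon rule tables for driver classification.
# These mirror the package defaults (ras_rules()); edit and pass the file
# path as `config` to override without code changes.
braf:
  class1: [600]
  class2: [464, 469, 597, 601]
  class3: [466, 581, 594, 595, 596]
  domain_A: [600]
  domain_B: [581, 582, 583, 584, 585, 586, 587, 588, 589, 590,
             591, 592, 593, 594, 595, 596, 597, 598, 599, 601]
  domain_C: [464, 466, 469]
kras:
  typical: [12, 13, 61]
  atypical: [14, 19, 22, 33, 34, 59, 60, 68, 117, 146, 147]
nras:
  pathogenic: [12, 13, 61]
nf1:
  # consequences counted as protein-truncating; drop "splice" to exclude
  # splice-site variants
  truncating_consequences: [nonsense, frameshift, splice]
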