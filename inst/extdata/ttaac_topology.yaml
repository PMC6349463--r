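# Fold annotation of the T. thermophila ADP/ATP carrier (author numbering,
# ranges inclusive on both ends). Helix spans are configurable annotations
# taken from the deposited model's helical regions.
protein: TtAac
helix_spans:
  H1: [16, 45]
  h12: [52, 62]
  H2: [74, 107]
  H3: [116, 145]
  h34: [155, 165]
  H4: [177, 211]
  H5: [220, 250]
  h56: [258, 268]
  H6: [273, 306]
domain_spans:
  D1: [13, 107]
  D2: [116, 211]
  D3: [220, 306]
contact_points:
  H2: 88
  H4: 192
  H6: 287
binding_site: [30, 88, 192, 193, 196, 238, 287]
matrix_network: [37, 40, 142, 145, 242, 245]
cytoplasmic_network: [101, 104, 205, 208, 299, 302]
braces: [100, 204, 298]
hydrophobic_plug: [97, 201, 295]
ceiling: [96, 200, 294]
signature_prolines: [35, 140, 240]
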