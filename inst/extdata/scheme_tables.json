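{
  "version": "1.0",
  "comment": "Region-definition tables for the numbering-lite annotator. Positions are 1-based. c1_window: allowed positions of the first conserved cysteine (FR1 end). fr2_len / fr3_len / fr4_len: fixed region lengths under the scheme. cdr*_range: allowed CDR lengths. fr4_first: allowed first FR4 residue (Phe for light J segments, Trp for heavy).",
  "imgt": {
    "c1_window": [21, 26],
    "cdr1_range": [5, 12],
    "fr2_len": 17,
    "cdr2_range": [1, 10],
    "fr3_len": 36,
    "cdr3_range": [4, 20],
    "fr4_len": 10,
    "fr4_first": ["F", "W"]
  },
  "kabat": {
    "c1_window": [21, 26],
    "cdr1_range": [5, 17],
    "fr2_len": 15,
    "cdr2_range": [1, 12],
    "fr3_len": 32,
    "cdr3_range": [4, 22],
    "fr4_len": 10,
    "fr4_first": ["F", "W"]
  }
}
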