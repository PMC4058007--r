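# Toxin category keyword rules, in priority order (first match wins).
# Keywords are matched case-insensitively as substrings of the best-hit
# description; hits above the e-value cutoff are never categorised.
# Edit freely: these defaults cover the classic black widow venom
# component families, but the exact text-search vocabulary of any given
# annotation source is a user choice, not a fixed truth.
- name: latrotoxin
  keywords: [latrotoxin, latroinsectotoxin]
- name: latrodectin
  keywords: [latrodectin]
- name: ICK/CSTX
  keywords: [cstx, ctenitoxin, knottin, cystine knot]
- name: CRISP
  keywords: [cysteine-rich secretory, crisp, venom allergen]
- name: hyaluronidase
  keywords: [hyaluronidase]
- name: chitinase
  keywords: [chitinase]
- name: serine protease
  keywords: [serine protease, trypsin, chymotrypsin]
- name: metalloprotease
  keywords: [metalloprotease, metalloproteinase, reprolysin, astacin]
- name: leucine-rich repeat
  keywords: [leucine-rich repeat, leucine rich repeat]
- name: other toxin
  keywords: [toxin, venom]
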