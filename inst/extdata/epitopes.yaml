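# Canonical DQ2.5 alpha-gliadin T-cell epitopes (9-mer cores).
# Additional epitopes (e.g. the DQ8 family) can be appended here; the
# scanner takes any config of name/class/sequence records.
- name: DQ2.5-Glia-a1a
  class: DQ2.5
  sequence: PFPQPQLPY
- name: DQ2.5-Glia-a1b
  class: DQ2.5
  sequence: PYPQPQLPY
- name: DQ2.5-Glia-a2
  class: DQ2.5
  sequence: PQPQLPYPQ
- name: DQ2.5-Glia-a3
  class: DQ2.5
  sequence: FRPQQPYPQ
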