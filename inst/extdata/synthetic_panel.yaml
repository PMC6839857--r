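loci:
- name: DYS19
  copy_number: 1
  variable: no
  mutation_rate: 0.002
- name: DYS389I
  copy_number: 1
  variable: no
  mutation_rate: 0.002
- name: DYS389II
  copy_number: 1
  variable: no
  mutation_rate: 0.002
- name: DYS390
  copy_number: 1
  variable: no
  mutation_rate: 0.002
- name: DYS385
  copy_number: 2
  variable: no
  mutation_rate: 0.002
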