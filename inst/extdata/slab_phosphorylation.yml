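compartments:
- name: cytosol
  kind: volume
  tag: 1
- name: membrane
  kind: surface
  tag: 2
  borders: cytosol
species:
- name: A
  compartment: cytosol
  D: 10.0
  initial: 1.0
- name: Ap
  compartment: cytosol
  D: 10.0
  initial: 0.0
parameters:
- name: kkin
  kind: constant
  value: 1.0
  unit: um/s
- name: kp
  kind: constant
  value: 1.0
  unit: 1/s
reactions:
- name: phosphorylation
  type: volume_surface
  compartment: membrane
  rate: kkin*A
  stoich:
    A: -1.0
    Ap: 1.0
  rate_unit: uM*um/s
- name: dephosphorylation
  type: volume
  compartment: cytosol
  rate: kp*Ap
  stoich:
    A: 1.0
    Ap: -1.0
  rate_unit: uM/s
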