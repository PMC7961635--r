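name: double_pendulum
segments:
- name: rod1
  mass: 1.0
  inertia:
  - 0.083333333333
  - 9.333333333333e-06
  - 8.333333333333e-02
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  com:
  - 0.0
  - -0.5
  - 0.0
  endpoints:
  - name: distal
    point:
    - 0.0
    - -1.0
    - 0.0
- name: rod2
  mass: 0.8
  inertia:
  - 0.042666666667
  - 5.266666666667e-06
  - 4.266666666667e-02
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  com:
  - 0.0
  - -0.4
  - 0.0
  endpoints:
  - name: tip
    point:
    - 0.0
    - -0.8
    - 0.0
joints:
- name: pin1
  type: revolute
  parent: ground
  child: rod1
  offset_parent:
  - 0.0
  - 0.0
  - 0.0
  offset_child:
  - 0.0
  - 0.0
  - 0.0
  axis:
  - 0.0
  - 0.0
  - 1.0
  range:
  - - -3.14159265359
    - 3.14159265359
- name: pin2
  type: revolute
  parent: rod1
  child: rod2
  offset_parent:
  - 0.0
  - -1.0
  - 0.0
  offset_child:
  - 0.0
  - 0.0
  - 0.0
  axis:
  - 0.0
  - 0.0
  - 1.0
  range:
  - - -3.14159265359
    - 3.14159265359
markers:
- name: elbow
  segment: rod1
  position:
  - 0.0
  - -1.0
  - 0.0
- name: tip
  segment: rod2
  position:
  - 0.0
  - -0.8
  - 0.0
imus: []
muscles: []
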