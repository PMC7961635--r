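name: pendulum
segments:
- name: rod
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
  - name: tip
    point:
    - 0.0
    - -1.0
    - 0.0
joints:
- name: pin
  type: revolute
  parent: ground
  child: rod
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
markers:
- name: tip
  segment: rod
  position:
  - 0.0
  - -1.0
  - 0.0
- name: mid
  segment: rod
  position:
  - 0.0
  - -0.5
  - 0.0
- name: side
  segment: rod
  position:
  - 0.1
  - -0.5
  - 0.0
imus:
- name: rod_imu
  segment: rod
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
muscles: []
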