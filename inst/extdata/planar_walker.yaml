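name: planar_walker
segments:
- name: pelvis
  mass: 50.85
  inertia:
  - 1.5255
  - 0.8136
  - 1.3221
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.0
  - 0.25
  - 0.0
  endpoints:
  - name: hip_r
    point:
    - 0.0
    - 0.0
    - 0.09
  - name: hip_l
    point:
    - 0.0
    - 0.0
    - -0.09
- name: thigh_r
  mass: 7.5
  inertia:
  - 0.15844966875
  - 0.007922483438
  - 0.15844966875
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.0
  - -0.19485
  - 0.0
  endpoints:
  - name: knee
    point:
    - 0.0
    - -0.45
    - 0.0
- name: shank_r
  mass: 3.4875
  inertia:
  - 0.058811873355
  - 0.002940593668
  - 0.058811873355
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.0
  - -0.18619
  - 0.0
  endpoints:
  - name: ankle
    point:
    - 0.0
    - -0.43
    - 0.0
- name: foot_r
  mass: 1.0875
  inertia:
  - 0.002
  - 0.005
  - 0.005
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.05
  - -0.05
  - 0.0
  endpoints:
  - name: heel
    point:
    - -0.05
    - -0.07
    - 0.0
  - name: mtp
    point:
    - 0.15
    - -0.07
    - 0.0
- name: thigh_l
  mass: 7.5
  inertia:
  - 0.15844966875
  - 0.007922483438
  - 0.15844966875
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.0
  - -0.19485
  - 0.0
  endpoints:
  - name: knee
    point:
    - 0.0
    - -0.45
    - 0.0
- name: shank_l
  mass: 3.4875
  inertia:
  - 0.058811873355
  - 0.002940593668
  - 0.058811873355
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.0
  - -0.18619
  - 0.0
  endpoints:
  - name: ankle
    point:
    - 0.0
    - -0.43
    - 0.0
- name: foot_l
  mass: 1.0875
  inertia:
  - 0.002
  - 0.005
  - 0.005
  - 0.0
  - 0.0
  - 0.0
  com:
  - 0.05
  - -0.05
  - 0.0
  endpoints:
  - name: heel
    point:
    - -0.05
    - -0.07
    - 0.0
  - name: mtp
    point:
    - 0.15
    - -0.07
    - 0.0
joints:
- name: base
  type: free_planar
  parent: ground
  child: pelvis
  offset_parent:
  - 0.0
  - 0.0
  - 0.0
  offset_child:
  - 0.0
  - 0.0
  - 0.0
  range:
  - - -10.0
    - 10.0
  - - 0.5
    - 1.5
  - - -3.14159265359
    - 3.14159265359
- name: hip_r
  type: revolute
  parent: pelvis
  child: thigh_r
  offset_parent:
  - 0.0
  - 0.0
  - 0.09
  offset_child:
  - 0.0
  - 0.0
  - 0.0
  axis:
  - 0.0
  - 0.0
  - 1.0
  range:
  - - -1.2
    - 1.2
- name: knee_r
  type: revolute
  parent: thigh_r
  child: shank_r
  offset_parent:
  - 0.0
  - -0.45
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
  - - -1.2
    - 1.2
- name: ankle_r
  type: revolute
  parent: shank_r
  child: foot_r
  offset_parent:
  - 0.0
  - -0.43
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
  - - -1.2
    - 1.2
- name: hip_l
  type: revolute
  parent: pelvis
  child: thigh_l
  offset_parent:
  - 0.0
  - 0.0
  - -0.09
  offset_child:
  - 0.0
  - 0.0
  - 0.0
  axis:
  - 0.0
  - 0.0
  - 1.0
  range:
  - - -1.2
    - 1.2
- name: knee_l
  type: revolute
  parent: thigh_l
  child: shank_l
  offset_parent:
  - 0.0
  - -0.45
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
  - - -1.2
    - 1.2
- name: ankle_l
  type: revolute
  parent: shank_l
  child: foot_l
  offset_parent:
  - 0.0
  - -0.43
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
  - - -1.2
    - 1.2
markers:
- name: pelvis_m1
  segment: pelvis
  position:
  - 0.08
  - 0.05
  - 0.1
- name: pelvis_m2
  segment: pelvis
  position:
  - 0.08
  - 0.05
  - -0.1
- name: pelvis_m3
  segment: pelvis
  position:
  - -0.1
  - 0.08
  - 0.0
- name: thigh_r_m1
  segment: thigh_r
  position:
  - 0.06
  - -0.1
  - 0.0
- name: thigh_r_m2
  segment: thigh_r
  position:
  - -0.05
  - -0.2
  - 0.03
- name: thigh_r_m3
  segment: thigh_r
  position:
  - 0.04
  - -0.35
  - -0.03
- name: shank_r_m1
  segment: shank_r
  position:
  - 0.05
  - -0.1
  - 0.0
- name: shank_r_m2
  segment: shank_r
  position:
  - -0.04
  - -0.25
  - 0.02
- name: shank_r_m3
  segment: shank_r
  position:
  - 0.03
  - -0.38
  - -0.02
- name: foot_r_m1
  segment: foot_r
  position:
  - -0.05
  - -0.07
  - 0.0
- name: foot_r_m2
  segment: foot_r
  position:
  - 0.15
  - -0.07
  - 0.0
- name: foot_r_m3
  segment: foot_r
  position:
  - 0.05
  - 0.02
  - 0.03
- name: thigh_l_m1
  segment: thigh_l
  position:
  - 0.06
  - -0.1
  - 0.0
- name: thigh_l_m2
  segment: thigh_l
  position:
  - -0.05
  - -0.2
  - 0.03
- name: thigh_l_m3
  segment: thigh_l
  position:
  - 0.04
  - -0.35
  - -0.03
- name: shank_l_m1
  segment: shank_l
  position:
  - 0.05
  - -0.1
  - 0.0
- name: shank_l_m2
  segment: shank_l
  position:
  - -0.04
  - -0.25
  - 0.02
- name: shank_l_m3
  segment: shank_l
  position:
  - 0.03
  - -0.38
  - -0.02
- name: foot_l_m1
  segment: foot_l
  position:
  - -0.05
  - -0.07
  - 0.0
- name: foot_l_m2
  segment: foot_l
  position:
  - 0.15
  - -0.07
  - 0.0
- name: foot_l_m3
  segment: foot_l
  position:
  - 0.05
  - 0.02
  - 0.03
imus:
- name: pelvis_imu
  segment: pelvis
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- name: thigh_r_imu
  segment: thigh_r
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- name: shank_r_imu
  segment: shank_r
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- name: foot_r_imu
  segment: foot_r
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- name: thigh_l_imu
  segment: thigh_l
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- name: shank_l_imu
  segment: shank_l
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
- name: foot_l_imu
  segment: foot_l
  orientation:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
muscles:
- name: hip_flex_r
  fmax: 2000.0
  path:
  - segment: pelvis
    point:
    - 0.06
    - 0.06
    - 0.09
  - segment: thigh_r
    point:
    - 0.05
    - -0.16
    - 0.0
- name: hip_ext_r
  fmax: 2000.0
  path:
  - segment: pelvis
    point:
    - -0.06
    - 0.06
    - 0.09
  - segment: thigh_r
    point:
    - -0.05
    - -0.16
    - 0.0
- name: knee_ext_r
  fmax: 3000.0
  path:
  - segment: thigh_r
    point:
    - 0.05
    - -0.3
    - 0.0
  - segment: shank_r
    point:
    - 0.05
    - -0.12
    - 0.0
- name: knee_flex_r
  fmax: 3000.0
  path:
  - segment: thigh_r
    point:
    - -0.05
    - -0.3
    - 0.0
  - segment: shank_r
    point:
    - -0.04
    - -0.12
    - 0.0
- name: ankle_dflex_r
  fmax: 1500.0
  path:
  - segment: shank_r
    point:
    - 0.04
    - -0.3
    - 0.0
  - segment: foot_r
    point:
    - 0.09
    - -0.05
    - 0.0
- name: ankle_pflex_r
  fmax: 3000.0
  path:
  - segment: shank_r
    point:
    - -0.04
    - -0.3
    - 0.0
  - segment: foot_r
    point:
    - -0.05
    - -0.06
    - 0.0
- name: hip_flex_l
  fmax: 2000.0
  path:
  - segment: pelvis
    point:
    - 0.06
    - 0.06
    - -0.09
  - segment: thigh_l
    point:
    - 0.05
    - -0.16
    - 0.0
- name: hip_ext_l
  fmax: 2000.0
  path:
  - segment: pelvis
    point:
    - -0.06
    - 0.06
    - -0.09
  - segment: thigh_l
    point:
    - -0.05
    - -0.16
    - 0.0
- name: knee_ext_l
  fmax: 3000.0
  path:
  - segment: thigh_l
    point:
    - 0.05
    - -0.3
    - 0.0
  - segment: shank_l
    point:
    - 0.05
    - -0.12
    - 0.0
- name: knee_flex_l
  fmax: 3000.0
  path:
  - segment: thigh_l
    point:
    - -0.05
    - -0.3
    - 0.0
  - segment: shank_l
    point:
    - -0.04
    - -0.12
    - 0.0
- name: ankle_dflex_l
  fmax: 1500.0
  path:
  - segment: shank_l
    point:
    - 0.04
    - -0.3
    - 0.0
  - segment: foot_l
    point:
    - 0.09
    - -0.05
    - 0.0
- name: ankle_pflex_l
  fmax: 3000.0
  path:
  - segment: shank_l
    point:
    - -0.04
    - -0.3
    - 0.0
  - segment: foot_l
    point:
    - -0.05
    - -0.06
    - 0.0
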