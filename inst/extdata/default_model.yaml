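segments:
- name: pelvis
  parent: ~
  joint:
    name: ground_pelvis
    type: free6
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - pelvis_tilt
    - pelvis_list
    - pelvis_rotation
    - pelvis_tx
    - pelvis_ty
    - pelvis_tz
  tfix:
  - 0.0
  - 0.0
  - 0.95
  Rfix_quat:
  - 0.707106781186548
  - 0.707106781186547
  - 0.0
  - 0.0
  length: 0.15
  imu:
    id: pelvis_imu
    pos:
    - -0.1
    - 0.05
    - 0.0
- name: torso
  parent: pelvis
  joint:
    name: back
    type: ball3
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - lumbar_extension
    - lumbar_bending
    - lumbar_rotation
  tfix:
  - 0.0
  - 0.1
  - 0.0
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.45
  imu:
    id: torso_imu
    pos:
    - -0.08
    - 0.35
    - 0.0
- name: femur_r
  parent: pelvis
  joint:
    name: hip_r
    type: ball3
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - hip_flexion_r
    - hip_adduction_r
    - hip_rotation_r
  tfix:
  - 0.0
  - -0.07
  - 0.084
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.4
  imu:
    id: thigh_r_imu
    pos:
    - 0.0
    - -0.2
    - 0.07
- name: femur_l
  parent: pelvis
  joint:
    name: hip_l
    type: ball3
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - hip_flexion_l
    - hip_adduction_l
    - hip_rotation_l
  tfix:
  - 0.0
  - -0.07
  - -0.084
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.4
  imu:
    id: thigh_l_imu
    pos:
    - 0.0
    - -0.2
    - -0.07
- name: tibia_r
  parent: femur_r
  joint:
    name: knee_r
    type: pin1
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - knee_flexion_r
  tfix:
  - 0.0
  - -0.4
  - 0.0
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.43
  imu:
    id: shank_r_imu
    pos:
    - 0.0
    - -0.22
    - 0.05
- name: tibia_l
  parent: femur_l
  joint:
    name: knee_l
    type: pin1
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - knee_flexion_l
  tfix:
  - 0.0
  - -0.4
  - 0.0
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.43
  imu:
    id: shank_l_imu
    pos:
    - 0.0
    - -0.22
    - -0.05
- name: foot_r
  parent: tibia_r
  joint:
    name: ankle_r
    type: pin1
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - ankle_flexion_r
  tfix:
  - 0.0
  - -0.43
  - 0.0
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.2
  imu:
    id: foot_r_imu
    pos:
    - 0.1
    - -0.03
    - 0.0
- name: foot_l
  parent: tibia_l
  joint:
    name: ankle_l
    type: pin1
    axis:
    - 0.0
    - 0.0
    - 1.0
    coords:
    - ankle_flexion_l
  tfix:
  - 0.0
  - -0.43
  - 0.0
  Rfix_quat:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  length: 0.2
  imu:
    id: foot_l_imu
    pos:
    - 0.1
    - -0.03
    - 0.0
coordinates:
- name: pelvis_tilt
  lb: -6.283185307179586
  ub: 6.283185307179586
  free: yes
- name: pelvis_list
  lb: -6.283185307179586
  ub: 6.283185307179586
  free: yes
- name: pelvis_rotation
  lb: -12.566370614359172
  ub: 12.566370614359172
  free: yes
- name: pelvis_tx
  lb: -5.0
  ub: 5.0
  free: no
- name: pelvis_ty
  lb: -5.0
  ub: 5.0
  free: no
- name: pelvis_tz
  lb: -5.0
  ub: 5.0
  free: no
- name: lumbar_extension
  lb: -1.570796326794897
  ub: 1.570796326794897
  free: yes
- name: lumbar_bending
  lb: -1.570796326794897
  ub: 1.570796326794897
  free: yes
- name: lumbar_rotation
  lb: -1.570796326794897
  ub: 1.570796326794897
  free: yes
- name: hip_flexion_r
  lb: -2.094395102393195
  ub: 2.094395102393195
  free: yes
- name: hip_adduction_r
  lb: -1.047197551196598
  ub: 1.047197551196598
  free: yes
- name: hip_rotation_r
  lb: -1.047197551196598
  ub: 1.047197551196598
  free: yes
- name: hip_flexion_l
  lb: -2.094395102393195
  ub: 2.094395102393195
  free: yes
- name: hip_adduction_l
  lb: -1.047197551196598
  ub: 1.047197551196598
  free: yes
- name: hip_rotation_l
  lb: -1.047197551196598
  ub: 1.047197551196598
  free: yes
- name: knee_flexion_r
  lb: 0.0
  ub: 2.443460952792061
  free: yes
- name: knee_flexion_l
  lb: 0.0
  ub: 2.443460952792061
  free: yes
- name: ankle_flexion_r
  lb: -1.047197551196598
  ub: 1.047197551196598
  free: yes
- name: ankle_flexion_l
  lb: -1.047197551196598
  ub: 1.047197551196598
  free: yes
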