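- name: PCr
  shifts_ppm:
  - 0.0
- name: ATP
  shifts_ppm:
  - -2.53
  - -7.56
  - -16.18
  j_hz:
  - - 0.0
    - 0.0
    - 16.3
  - - 0.0
    - 0.0
    - 16.3
  - - 16.3
    - 16.3
    - 0.0
- name: NAD+
  shifts_ppm:
  - -8.33
  - -8.27
  j_hz:
  - - 0.0
    - 20.0
  - - 20.0
    - 0.0
- name: NADH
  shifts_ppm:
  - -8.18
  - -8.12
  j_hz:
  - - 0.0
    - 20.0
  - - 20.0
    - 0.0
- name: UDPG
  shifts_ppm:
  - -9.8
  - -11.6
  j_hz:
  - - 0.0
    - 20.0
  - - 20.0
    - 0.0
- name: GPC
  shifts_ppm:
  - 2.95
  proton_multiplet:
  - 3.0
  - 6.3
- name: GPE
  shifts_ppm:
  - 3.5
  proton_multiplet:
  - 3.0
  - 7.3
- name: Pi_ex
  shifts_ppm:
  - 5.25
- name: Pi_in
  shifts_ppm:
  - 4.85
- name: PC
  shifts_ppm:
  - 6.24
  proton_multiplet:
  - 3.0
  - 6.3
- name: PE
  shifts_ppm:
  - 6.78
  proton_multiplet:
  - 3.0
  - 7.3
- name: MP
  shifts_ppm:
  - 1.7
  broad: yes
  broad_fwhm_hz: 450.0
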