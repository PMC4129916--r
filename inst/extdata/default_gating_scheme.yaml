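protocol_id: ~
gates:
- name: PicoFLO
  x_axis: max_FWS
  y_axis: ratio_FLO_SWS
  x_scale: log10
  y_scale: log10
  priority: 1
  vertices:
  - - 0.4
    - 0.5
  - - 1.6
    - 0.5
  - - 1.6
    - 2.2
  - - 0.4
    - 2.2
- name: HighSWS
  x_axis: max_SWS
  y_axis: max_FLR
  x_scale: log10
  y_scale: log10
  priority: 2
  vertices:
  - - 2.9
    - 1.5
  - - 4.0
    - 1.5
  - - 4.0
    - 2.7
  - - 2.9
    - 2.7
- name: HighFLO
  x_axis: total_FWS
  y_axis: total_FLO
  x_scale: log10
  y_scale: log10
  priority: 3
  vertices:
  - - 2.9
    - 3.2
  - - 4.1
    - 3.2
  - - 4.1
    - 4.4
  - - 2.9
    - 4.4
- name: Picoeukaryotes
  x_axis: total_FWS
  y_axis: total_FLR
  x_scale: log10
  y_scale: log10
  priority: 4
  vertices:
  - - 1.35
    - 0.7
  - - 2.45
    - 0.7
  - - 2.45
    - 1.8
  - - 1.35
    - 1.8
- name: Nanophytoplankton
  x_axis: total_FWS
  y_axis: total_FLR
  x_scale: log10
  y_scale: log10
  priority: 5
  vertices:
  - - 2.6
    - 2.6
  - - 3.8
    - 2.6
  - - 3.8
    - 3.8
  - - 2.6
    - 3.8
- name: Microphytoplankton
  x_axis: total_FWS
  y_axis: total_FLR
  x_scale: log10
  y_scale: log10
  priority: 6
  vertices:
  - - 4.0
    - 3.6
  - - 5.2
    - 3.6
  - - 5.2
    - 4.8
  - - 4.0
    - 4.8
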