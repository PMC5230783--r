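# Reference 7 T protocols (0.6 mm isotropic). Units: seconds, degrees,
# Hz/pixel. One document per sequence; read with memp2rage::read_protocol()
# on a single-document extract or yaml::read_yaml() for the full list.
me_mp2rage:
  sequence_kind: me_mp2rage
  T_R_seq: 6.0
  T_I_1: 0.75
  T_I_2: 2.90
  alpha_1: 4.0
  alpha_2: 6.0
  T_R_gre: 0.0181
  n_lines: 114
  n_echoes: 4
  T_E_first: 0.00235
  delta_T_E: 0.00414
  bandwidth: 280.0
  inv_efficiency: 1.0
  flip_accuracy: 1.0
  center_fraction: 0.3333333333333333
mp2rage:
  sequence_kind: mp2rage
  T_R_seq: 5.0
  T_I_1: 0.80
  T_I_2: 2.40
  alpha_1: 4.0
  alpha_2: 4.0
  T_R_gre: 0.0059
  n_lines: 105
  n_echoes: 1
  T_E_first: 0.00235
  delta_T_E: 0.0
  bandwidth: 280.0
  inv_efficiency: 1.0
  flip_accuracy: 1.0
  center_fraction: 0.5
me_flash:
  sequence_kind: me_flash
  alpha_1: 11.0
  T_R_gre: 0.031
  n_echoes: 5
  T_E_first: 0.003
  delta_T_E: 0.006
  bandwidth: 200.0
  inv_efficiency: 1.0
  flip_accuracy: 1.0
  center_fraction: 0.5
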