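# Published stress-free open-sector geometries of the rabbit carotid
# for a range of opening angles, all corresponding to the same
# unloaded annulus (r_i 0.7395, t_m 0.2593, t_a 0.1197 mm).
# Units: mm and degrees.
geometries:
  - {alpha: 0,   R_i: 0.7395, T_m: 0.2593, T_a: 0.1197}
  - {alpha: 40,  R_i: 0.8472, T_m: 0.2595, T_a: 0.1221}
  - {alpha: 80,  R_i: 0.9858, T_m: 0.2597, T_a: 0.1246}
  - {alpha: 120, R_i: 1.1708, T_m: 0.2599, T_a: 0.1272}
  - {alpha: 160, R_i: 1.4300, T_m: 0.2600, T_a: 0.1300}
  - {alpha: 200, R_i: 1.8191, T_m: 0.2601, T_a: 0.1329}
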