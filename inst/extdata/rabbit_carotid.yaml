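# Two-layer rabbit carotid artery: published geometry and material set.
# Units: radii and thicknesses mm, stiffnesses and tractions kPa,
# separation energy N/mm, angles degrees.
# The unloaded (residually-stressed) annulus is given at 4-decimal
# precision; the stress-free sector carries an opening angle of 160.
geometry:
  stress_free:
    R_i: 1.4300
    T_m: 0.2600
    T_a: 0.1300
    alpha: 160
  unloaded:
    r_i: 0.7395
    t_m: 0.2593
    t_a: 0.1197
materials:
  media:
    c: 1.5
    k1: 2.3632
    k2: 0.8393
    beta: 29
    T_c: 3.0
    G_c: 0.001
    du_c: 0.667
  adventitia:
    c: 0.15
    k1: 0.5620
    k2: 0.7112
    beta: 62
    T_c: 0.3
    G_c: 0.0001
    du_c: 0.667
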