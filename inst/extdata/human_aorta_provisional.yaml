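# Aged human thoracic aorta parameter set -- PROVISIONAL.
# The published source table's numeric formatting is ambiguous for
# several fields; only values that parse unambiguously are stored.
# Everything else is listed under 'unparsed' rather than guessed.
provisional: true
alpha: 80
cohesive_rule: "T_c = 2 * c_media"
G_c:
  media: 0.001
  adventitia: 0.0001
thickness_mm:
  media: 0.69
  adventitia: 0.48
R_i_mm: 1.13
notes: >
  The media matrix stiffness is much greater than in the rabbit
  carotid set.  HGO constants (c, k1, k2, beta) per layer could not be
  parsed with confidence and are deliberately omitted.
unparsed: [c, k1, k2, beta, T_c]
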