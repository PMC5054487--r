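# Permeability classification rules for pathway metabolites.
#
# Classes, from most to least membrane-permeable: H, MH, ML, L.
# All comparisons are strict (<); a descriptor exactly on a threshold falls
# into the less-permeable alternative and is flagged by the classifier.
#
# one_param: ladder on the topological polar surface area alone
#   (TPSA in A^2; higher TPSA = more polar = less permeable).
# three_param: ordered decision list on TPSA, logP and molecular weight
#   (first matching rule wins; the last rule has no condition).  The logP and
#   MW cut-offs are a calibrated convention chosen to reproduce the reference
#   classification of the tryptophan-pathway intermediates with OpenBabel
#   descriptors of the pinned (charged) species; they are not a mechanistic
#   permeability model.
classes: [H, MH, ML, L]
one_param:
  tpsa: [60.0, 120.0, 200.0]
three_param:
  rules:
    - {class: H, tpsa_max: 60.0}
    - {class: H, tpsa_max: 120.0, logp_max: 1.0}
    - {class: MH, tpsa_max: 160.0, logp_max: 1.7}
    - {class: ML, tpsa_max: 250.0, mw_max: 500.0}
    - {class: L}
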