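# Event tallies transcribed from the reference in vivo study (categorical
# outcomes scored on live time-lapses). Numerator/denominator pairs; digits
# give the printed precision of the reported percentage.
tallies:
  - name: reopening_during_pulse
    description: phagosomes whose re-opening was visualised during a pulse
    numerator: 27
    denominator: 138
    digits: 1
    expected_pct: 19.6
  - name: full_release_during_pulse
    description: pulses in which bacteria were fully released before re-capture
    numerator: 7
    denominator: 138
    digits: 1
    expected_pct: 5.1
  - name: recaptured_same_neutrophil
    description: released bacteria re-captured by the same neutrophil
    numerator: 29
    denominator: 31
    digits: 0
    expected_pct: 94
  - name: tubule_neck_during_pulse
    description: phagosome necks forming an elongate tubule during a pulse
    numerator: 3
    denominator: 31
    digits: 1
    expected_pct: 9.7
  - name: released_to_other_phagocyte
    description: released bacteria re-phagocytosed by a non-neutrophil phagocyte
    numerator: 1
    denominator: 31
    digits: 0
    expected_pct: 3
  - name: shuttled_to_other_neutrophil
    description: released bacteria shuttled into another neutrophil
    numerator: 1
    denominator: 31
    digits: 0
    expected_pct: 3
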