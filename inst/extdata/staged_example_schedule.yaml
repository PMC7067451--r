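# Staged scenario: normal breathing, then early periodic breathing
# (h = 0.5), then severe Cheyne-Stokes respiration with apneas (h = 1.5).
phi_m: 0
segments:
  - start_s: 0
    end_s: 120
    h: 0
    f_m: 0.01
  - start_s: 120
    end_s: 660
    h: 0.5
    f_m: 0.01
  - start_s: 660
    end_s: 900
    h: 1.5
    f_m: 0.01
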