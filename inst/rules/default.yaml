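# Default MR sequence weighting rules. Ordered; first match wins; the final
# rule is the mandatory catch-all. Times in ms, angles in degrees. max_b is
# the largest diffusion b-value of the sequence (absent b-values compare as
# -Inf). TI windows cover both 1.5 T and 3 T conventions.
rules:
  - name: diffusion
    when:
      max_b: {gt: 50}
    token: DWI
  - name: flair
    when:
      inversion_recovery: true
      ti_ms: {ge: 1800, le: 2800}
    token: FLAIR
  - name: stir
    when:
      inversion_recovery: true
      ti_ms: {ge: 120, le: 300}
    token: STIR
  - name: t1-spin-echo
    when:
      technique: [SE, TSE]
      tr_ms: {lt: 800}
      te_ms: {lt: 30}
    token: T1
  - name: t2
    when:
      tr_ms: {gt: 2000}
      te_ms: {gt: 80}
    token: T2
  - name: proton-density
    when:
      tr_ms: {gt: 2000}
      te_ms: {lt: 30}
    token: PD
  - name: t1-gradient-echo
    when:
      technique: [GRE]
      flip_deg: {gt: 50}
      tr_ms: {lt: 800}
    token: T1
  - name: catch-all
    when: {}
    token: OTHER
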