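# Small demonstration log with one planted overlap pair per region.
seed: 7
n_scanners: 3
n_sites: 2
regions:
  spine:
    n_protocols: 6
    n_exams: 120
    code_vocabulary_size: 40
    cardinality_distribution: {"1": 0.9, "2": 0.1}
    protocol_frequency_range: [6, 60]
    planted_overlaps:
      - {i: 1, j: 2, oc: 0.5}
tree:
  n_protocols_per_scanner: 20
  sequences_per_protocol: [3, 6]
  n_core_parameter_tuples: 25
  synonyms_per_tuple: 3
  synonym_noise_rate: 0.5
  site_specific_sequence_rate: 0.2
  protocol_name_overlap: 0.8
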