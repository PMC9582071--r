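# Study-scale generator conditions: a six-month, three-scanner practice
# extract. These mirror the package defaults; see ?synthetic_config.
seed: 1
n_scanners: 3
n_sites: 2
regions:
  spine:
    n_protocols: 18
    n_exams: 727
    code_vocabulary_size: 127
    cardinality_distribution: {"1": 0.9, "2": 0.1}
    protocol_frequency_range: [6, 341]
  brain/head:
    n_protocols: 16
    n_exams: 249
    code_vocabulary_size: 98
    cardinality_distribution: {"1": 0.8, "2": 0.2}
    protocol_frequency_range: [6, 120]
tree:
  n_protocols_per_scanner: 100
  sequences_per_protocol: [3, 8]
  n_core_parameter_tuples: 110
  synonyms_per_tuple: 2
  synonym_noise_rate: 0.5
  site_specific_sequence_rate: 0.15
  protocol_name_overlap: 0.8
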