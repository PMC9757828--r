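# ShortStack-style hairpin RNA annotation predicates.
# Thresholds are editable; values follow the cited tool's published defaults
# where stated, otherwise common practice for plant miRNA annotation.
name: shortstack
duplex_read_precision: 0.75
star_expression_required: 1
max_duplex_mismatches: 5
max_asymmetric_bulge: 3
hairpin_length_range: [50, 300]
mas_length_range: [20, 24]
replication_required: false
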