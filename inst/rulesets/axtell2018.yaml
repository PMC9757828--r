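# Plant miRNA annotation criteria in the style of the revised community
# guidelines (strict duplex structure, sequenced star, replication).
name: axtell2018
duplex_read_precision: 0.75
star_expression_required: 1
max_duplex_mismatches: 5
max_asymmetric_bulge: 3
hairpin_length_range: [50, 300]
mas_length_range: [20, 24]
replication_required: true
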