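# Default DefenseKit thresholds; any key may be overridden.
# Load with readDefenseConfig().
countable_window: [3, 100]
protection_log10: 1
eop_modest: 0.01
sfc_modest: 0.5
epsilon_wt_threshold: 0.01
sfc_use_area: false
od_floor: 0.01
identity_threshold: 0.90
coverage_threshold: 0.80
gap_opening: 11
gap_extension: 1
max_content_diff: 3
min_flank_orfs: 10
neighborhood_flank: 50
dr_min_len: 16
dr_max_len: 20
dr_max_mismatch: 1
max_span: 200000
anchor_tail: 25
anchor_ext: 5
multcomp_method: dunnett
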