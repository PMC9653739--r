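feature	fixture	length_bp	approximate
rescue_endpoint_deletion	inversion1	53	FALSE
rescue_endpoint_tandem_duplication	inversion1	45	FALSE
orf200_3prime_inverted_repeat	inversion1	118	FALSE
trnC_rpoB_transposed_copy	inversion1	64	FALSE
trnV_ndhC_deletion	inversion2	152	FALSE
rpl23_remnant	inversion3	29	FALSE
stem_loop_arm	inversion4	7	FALSE
rpoB_trnC_marker_segment	inversion4	340	TRUE
ir_inversion_stem	ir_inversions	15	FALSE
terminal_13bp_match	inversion5	13	FALSE
flank_deletion	inversion5	68	FALSE
orf_core	inversion5	300	FALSE
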