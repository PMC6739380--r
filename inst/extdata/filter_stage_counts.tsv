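stage	removed	remaining
total		77204
drop_low_quality	0
drop_unconfirmed_transcript	20730
drop_utr	14597
functionally_annotated		41877
high_confidence		34725
non_synonymous		17373
drop_minor_in_reference		16319
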