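category	count
subjects	9
all_variants	77204
not_confirmed_transcript	20730
utr	14597
functionally_annotated	41877
synonymous	20748
non_synonymous	21129
missense	19751
nonsense	240
frameshift	612
inframe	447
stop_loss	59
stop_gain	20
rare	5914
novel	3345
deletion	645
insertion	413
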