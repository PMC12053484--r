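marker	threshold	n_shuffles	calib_seed
IHF_54	34.2270593490831	10000	20241
MCP	35.6061591714112	10000	20241
portal	35.5862086491581	10000	20241
TerL	35.3252597032817	10000	20241
primase	35.2584687825063	10000	20241
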