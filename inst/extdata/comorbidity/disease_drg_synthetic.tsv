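disease	drg	surgical
AMI	121	FALSE
AMI	122	FALSE
AMI	123	FALSE
AMI	106	TRUE
AMI	112	TRUE
COPD	88	FALSE
COPD	96	FALSE
COPD	75	TRUE
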