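drg
104
105
106
107
108
110
111
112
75
76
77
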