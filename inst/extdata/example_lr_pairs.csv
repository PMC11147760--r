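pair_id,partner_a,partner_b,source
LR001,G0001,G0101,synthetic
LR002,G0002,G0102+G0103,synthetic
LR003,G0003,G0104,synthetic
LR004,G0004+G0005,G0105,synthetic
LR005,G0006,G0106,synthetic
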