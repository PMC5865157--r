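name,proton_affinity,forms_dimers
water,697,FALSE
methane,552,FALSE
methanol,761,TRUE
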