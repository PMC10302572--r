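condition,growth_rate_per_h,growth_rate_sd
glutamine,0.11,0.02
alanine,0.52,0.01
glycerol,0.65,0.02
glucose,0.93,0.06
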