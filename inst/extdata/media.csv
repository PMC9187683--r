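name,refractive_index,density,radiation_length
water,1.33,1.0,36.08
polyvinyl_toluene,1.58,1.032,43.79
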