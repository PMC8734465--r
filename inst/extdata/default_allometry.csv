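species_code,form,a,b
*,power_law,0.1,2.4
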