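label,kind,temperature_K,dlp0_M,rlp0_M,vp7_0_M,efficiency,condition
standard,assembly,298.15,1e-11,,7.8e-9,0.48,pH 5.5 / NaCl 0.1 M / Ca2+ 1 mM
high_pH,assembly,298.15,1e-11,,7.8e-9,<0.10,pH 8.0 / NaCl 0.1 M / Ca2+ 1 mM
high_NaCl,assembly,298.15,1e-11,,7.8e-9,,pH 5.5 / NaCl 0.5 M / Ca2+ 1 mM
high_Ca,assembly,298.15,1e-11,,7.8e-9,,pH 5.5 / NaCl 0.1 M / Ca2+ 5 mM
high_T,assembly,308.15,1e-11,,7.8e-9,<0.10,pH 5.5 / NaCl 0.1 M / Ca2+ 1 mM
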