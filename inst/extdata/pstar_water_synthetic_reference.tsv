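# Reference electronic stopping power and CSDA range for liquid water,
# hand-transcribed from the published NIST PSTAR tabulation (synthetic
# fixture: values copied to this file, not downloaded at build time).
energy_MeV	stopping_power_MeV_cm2_g	csda_range_g_cm2
100	7.289	7.718
150	5.445	15.77
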