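code,voltage_V,frequency_Hz,pulse_ms,I_measured_A
1V_20Hz,1,20,3.6,0.012
1V_7.9Hz,1,7.9,10,0.012
5V_20Hz,5,20,3.6,0.067
5V_7.9Hz,5,7.9,10,0.069
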