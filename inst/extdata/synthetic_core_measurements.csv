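sample_id,length_cm,d_min_mm,d_max_mm,mass_ambient_g,mass_ovendry_g
S000001,6.11,5.08,5.08,0.80320,0.73680
S000002,4.95,4.92,5.11,0.52110,0.47830
S000003,8.40,5.05,5.06,1.10240,1.01150
S000004,2.70,5.08,5.20,0.29980,0.27510
S000005,12.35,5.00,5.12,1.64070,1.50520
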