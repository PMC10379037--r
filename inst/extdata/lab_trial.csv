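n_samples,t_linear,t_pchip,t_makima,t_real,e_linear,e_pchip,e_makima
4,17.28,11.47,7.1,8,116,43.375,-11.25
5,14.17,9.6,6.85,8,77.125,20,-14.375
6,11.3,8.65,8.1,8,41.25,8.125,1.25
7,9.1,8.15,8.2,8,13.75,1.875,2.5
8,8.71,8.55,8.65,8,8.875,6.875,8.125
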