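date,tank,n_samples,t_linear,t_pchip,t_makima,t_real,e_linear,e_pchip,e_makima
2017-10-23,Coc_3,7,7.42,6.71,6.67,6.92,7.23,-3.03,-3.61
2017-10-23,Coc_4,7,7,5.35,5.04,4.75,47.37,12.63,6.11
2017-10-23,Coc_6,7,6.1,5.73,5.95,6.59,-7.44,-13.05,-9.71
2017-10-23,Coc_8,7,10.53,8.55,7.83,7.5,40.40,14.00,4.40
2017-10-25,Coc_5,8,7.68,6.25,6.06,5.92,29.73,5.57,2.36
2017-10-25,Coc_8,8,10.29,9.03,9.26,8.33,23.53,8.40,11.16
2017-10-25,Coc_9,8,7.53,6.33,6.41,6.17,22.04,2.59,3.89
2017-10-25,Coc_10,8,6.78,5.98,5.97,6,13.00,-0.33,-0.50
2017-11-02,Coc_8,8,5.91,5.55,5.53,5.67,4.23,-2.12,-2.47
2017-11-02,Coc_9,8,7.69,6.26,6.35,5.5,39.82,13.82,15.45
2017-11-02,Coc_10,8,6.91,6.43,6.37,6.16,12.18,4.38,3.41
2017-11-02,Coc_13,8,6.25,5.63,5.78,5.83,7.20,-3.43,-0.86
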