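energy_kev,mu_over_rho_cm2_g
10,187.0
15,61.0
20,28.3
30,9.48
35.983,5.60
35.987,31.3
40,23.0
50,13.6
60,8.39
80,3.89
100,2.150
150,0.861
200,0.484
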