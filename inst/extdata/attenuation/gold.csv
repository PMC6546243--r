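energy_kev,mu_over_rho_cm2_g
4,380.0
6,132.0
8,190.0
10,113.7
11.91,67.3
11.93,357.0
15,180.0
20,78.83
30,25.71
40,11.57
50,6.44
60,4.088
80.71,1.746
80.73,8.60
100,5.16
150,1.86
200,0.921
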