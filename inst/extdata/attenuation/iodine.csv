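energy_kev,mu_over_rho_cm2_g
10,169.0
15,55.1
20,25.6
30,8.561
33.168,6.40
33.172,35.8
40,22.1
50,12.32
60,7.579
80,3.510
100,1.942
150,0.7780
200,0.4370
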