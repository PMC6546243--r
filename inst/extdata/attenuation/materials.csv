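material,density_g_cm3
water,1.000
aluminium,2.699
silicon,2.330
tungsten,19.30
gold,19.32
caesium,1.873
iodine,4.933
csi,4.510
pom,1.410
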