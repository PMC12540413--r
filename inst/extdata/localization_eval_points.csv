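id,true_x,true_y,true_z,meas_x,meas_y,meas_z
1,1.000,2.000,1.000,1.010,1.990,0.990
2,1.000,2.000,2.000,0.990,2.030,1.960
3,1.000,2.000,3.000,1.020,2.030,2.950
4,1.000,2.000,4.000,1.020,2.040,4.150
5,1.000,2.000,5.000,0.960,2.070,5.180
6,1.000,2.000,6.000,1.030,1.920,5.780
7,1.000,2.000,7.000,1.040,1.930,7.260
8,1.000,2.000,8.000,0.970,2.080,7.650
9,1.000,2.000,9.000,1.060,2.110,9.350
10,1.000,2.000,10.000,0.950,2.120,9.430
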