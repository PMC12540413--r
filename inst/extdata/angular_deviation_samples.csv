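stage,theta_deg
a,-3.9
a,0.9
a,1.0
a,-5.0
b,4.8
b,3.0
b,3.9
b,0.1
c,1.9
c,-7.0
c,-4.9
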