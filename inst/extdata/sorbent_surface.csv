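term,estimate
intercept,41.80
A,-0.50
B,-1.50
C,-2.75
AB,-0.50
AC,1.00
BC,0.00
A2,-7.90
B2,-8.40
C2,-2.90
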