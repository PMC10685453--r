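#! FIELDS time extra cv_ring cv_tail
#! SET temperature 310
0 9.9 1.5 -2.25
0.5 8.8 1.625 -2.125
1 7.7 1.75 -2
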