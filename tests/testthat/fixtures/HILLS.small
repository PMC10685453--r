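#! FIELDS time cv_cq sigma_cv_cq height biasf
#! SET temperature 310
#! SET pace 2
2 0.25 0.5 1.2 20
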