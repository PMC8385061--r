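variable,category,count
histology,invasive_ductal_carcinoma,32
histology,invasive_lobular_carcinoma,4
stage,0,2
stage,I,22
stage,IIIa,4
stage,IIIb,1
stage,IIIc,3
stage,IVa,1
stage,undetermined,3
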