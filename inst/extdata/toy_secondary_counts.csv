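mirna_id,condition,treatment,replicate,duplicate,live,dead
synthetic-mir-1,light,mimic,1,1,80,20
synthetic-mir-1,light,mimic,2,1,76,24
synthetic-mir-1,light,mimic,3,1,78,22
synthetic-mir-1,dark,mimic,1,1,90,10
synthetic-mir-1,dark,mimic,2,1,88,12
synthetic-mir-1,dark,mimic,3,1,89,11
synthetic-mir-1,light,negative_mimic,1,1,60,40
synthetic-mir-1,light,negative_mimic,2,1,58,42
synthetic-mir-1,light,negative_mimic,3,1,56,44
synthetic-mir-1,dark,negative_mimic,1,1,90,10
synthetic-mir-1,dark,negative_mimic,2,1,89,11
synthetic-mir-1,dark,negative_mimic,3,1,88,12
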