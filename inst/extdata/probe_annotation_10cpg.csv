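cpg_id,chromosome,snp_maf,cross_reactive,region_class,gene
cg0000001,1,0.05,FALSE,promoter,TCF7
cg0000002,2,0.05,FALSE,body,RUNX1
cg0000003,X,NA,FALSE,other,NA
cg0000004,3,NA,TRUE,promoter,TOX
cg0000005,4,0.005,FALSE,body,SMAD3
cg0000006,5,NA,FALSE,promoter,GRAP2
cg0000007,6,NA,FALSE,other,NA
cg0000008,7,NA,FALSE,body,LEF1
cg0000009,8,NA,FALSE,promoter,IL7R
cg0000010,9,NA,FALSE,other,NA
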