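cpg_id,CD4,CD8
ref_cg001,0.2478,0.8779
ref_cg002,0.1295,0.809
ref_cg003,0.0731,0.9493
ref_cg004,0.0639,0.9312
ref_cg005,0.0987,0.9477
ref_cg006,0.2084,0.7631
ref_cg007,0.118,0.8754
ref_cg008,0.2444,0.8481
ref_cg009,0.0832,0.9442
ref_cg010,0.1418,0.8224
ref_cg011,0.7843,0.186
ref_cg012,0.7963,0.1027
ref_cg013,0.9046,0.0871
ref_cg014,0.7693,0.087
ref_cg015,0.8407,0.1259
ref_cg016,0.7669,0.2194
ref_cg017,0.8621,0.1496
ref_cg018,0.7517,0.2081
ref_cg019,0.9471,0.2177
ref_cg020,0.8133,0.1414
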