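cpg_id	S1	S2	S3	S4
cg0000001	0.8733	0.462	0.8636	0.7138
cg0000002	0.8934	0.6972	0.1748	0.7799
cg0000003	0.3075	0.8912	0.94	0.3993
cg0000004	0.7974	0.2799	0.902	0.6667
cg0000005	0.6276	0.4661	0.1242	0.0536
cg0000006	0.5172	0.896	0.5128	0.7996
cg0000007	0.7129	0.9304	0.4012	0.0566
cg0000008	0.1712	0.1557	0.8652	0.2369
cg0000009	0.6413	0.4775	0.4523	0.8659
cg0000010	0.6846	0.5543	0.8024	0.6006
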