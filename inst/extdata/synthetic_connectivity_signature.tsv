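gene_id	direction
gene0001	up
gene0002	up
gene0003	up
gene0004	up
gene0005	up
gene0006	up
gene0007	up
gene0008	up
gene0009	up
gene0010	up
gene0011	up
gene0012	up
gene0013	up
gene0014	up
gene0015	up
gene0016	up
gene0017	up
gene0018	up
gene0019	up
gene0020	up
gene0022	up
gene0023	up
gene0024	up
gene0025	up
gene0026	up
gene0027	up
gene0028	up
gene0029	up
gene0030	up
gene0031	up
gene0032	up
gene0033	up
gene0034	up
gene0035	up
gene0036	up
gene0037	up
gene0038	up
gene0039	up
gene0040	up
gene0041	down
gene0042	down
gene0043	down
gene0044	down
gene0045	down
gene0046	down
gene0047	down
gene0048	down
gene0049	down
gene0050	down
gene0051	down
gene0052	down
gene0053	down
gene0054	down
gene0055	down
gene0056	down
gene0057	down
gene0058	down
gene0059	down
gene0060	down
gene0061	down
gene0062	down
gene0063	down
gene0064	down
gene0065	down
gene0066	down
gene0067	down
gene0068	down
gene0069	down
gene0070	down
gene0071	down
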