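gene1	gene2	ka	ks	ka_ks	class
GrMYB012	GrMYB167	0.20	0.67	0.29	segmental
GrMYB013	GrMYB082	0.27	0.98	0.27	segmental
GrMYB015	GrMYB096	0.16	0.30	0.52	segmental
GrMYB016	GrMYB054	0.17	0.42	0.41	segmental
GrMYB017	GrMYB099	0.16	0.37	0.42	segmental
GrMYB021	GrMYB084	0.14	0.33	0.42	segmental
GrMYB022	GrMYB075	0.17	0.64	0.27	segmental
GrMYB030	GrMYB068	0.18	0.60	0.30	segmental
GrMYB031	GrMYB115	0.11	0.41	0.26	segmental
GrMYB040	GrMYB048	0.23	0.49	0.46	segmental
GrMYB046	GrMYB116	0.24	0.36	0.65	segmental
GrMYB061	GrMYB129	0.12	0.34	0.36	segmental
GrMYB065	GrMYB088	0.16	0.56	0.29	segmental
GrMYB067	GrMYB187	0.12	0.38	0.31	segmental
GrMYB069	GrMYB124	0.17	0.30	0.58	segmental
GrMYB074	GrMYB177	0.17	0.35	0.48	segmental
GrMYB078	GrMYB087	0.28	0.71	0.40	segmental
GrMYB093	GrMYB128	0.22	0.52	0.42	segmental
GrMYB094	GrMYB102	0.11	0.46	0.24	segmental
GrMYB103	GrMYB117	0.19	0.41	0.47	segmental
GrMYB138	GrMYB168	0.17	0.49	0.34	segmental
GrMYB139	GrMYB174	0.16	0.39	0.40	segmental
GrMYB145	GrMYB191	0.17	0.40	0.42	segmental
GrMYB148	GrMYB155	0.15	0.67	0.22	segmental
GrMYB150	GrMYB195	0.14	0.41	0.33	segmental
GrMYB151	GrMYB164	0.11	0.19	0.57	segmental
GrMYB183	GrMYB189	0.27	0.54	0.51	segmental
GrMYB008	GrMYB009	0.18	0.43	0.41	tandem
GrMYB049	GrMYB050	0.10	0.30	0.32	tandem
GrMYB052	GrMYB053	0.10	0.15	0.64	tandem
GrMYB057	GrMYB058	0.03	0.04	0.76	tandem
GrMYB109	GrMYB110	0.07	0.12	0.53	tandem
GrMYB135	GrMYB136	0.14	0.36	0.39	tandem
GrMYB184	GrMYB185	0.02	0.03	0.67	tandem
GrMYB197	GrMYB198	0.13	0.27	0.47	tandem
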