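gene	disease
GENE0001	Disease 0036
GENE0002	Disease 0033
GENE0003	Disease 0024
GENE0004	Disease 0038
GENE0007	Disease 0020
GENE0011	Disease 0037
GENE0012	Disease 0013
GENE0014	Disease 0010
GENE0017	Disease 0004
GENE0017	Disease 0010
GENE0018	Disease 0005
GENE0020	Disease 0014
GENE0020	Disease 0030
GENE0022	Disease 0030
GENE0023	Disease 0001
GENE0024	Disease 0001
GENE0031	Disease 0001
GENE0032	Disease 0031
GENE0033	Disease 0024
GENE0034	Disease 0017
GENE0036	Disease 0026
GENE0037	Disease 0012
GENE0038	Disease 0015
GENE0040	Disease 0023
GENE0042	Disease 0039
GENE0044	Disease 0024
GENE0050	Disease 0011
GENE0052	Disease 0023
GENE0053	Disease 0035
GENE0054	Disease 0025
GENE0060	Disease 0009
GENE0062	Disease 0013
GENE0065	Disease 0040
GENE0068	Disease 0001
GENE0072	Disease 0033
GENE0073	Disease 0034
GENE0073	Disease 0037
GENE0075	Disease 0039
GENE0077	Disease 0010
GENE0078	Disease 0025
GENE0080	Disease 0035
GENE0081	Disease 0021
GENE0082	Disease 0004
GENE0087	Disease 0018
GENE0091	Disease 0005
GENE0091	Disease 0026
GENE0092	Disease 0011
GENE0093	Disease 0015
GENE0094	Disease 0033
GENE0097	Disease 0031
GENE0100	Disease 0012
GENE0100	Disease 0021
GENE0101	Disease 0032
GENE0105	Disease 0001
GENE0107	Disease 0040
GENE0108	Disease 0011
GENE0116	Disease 0024
GENE0119	Disease 0033
GENE0120	Disease 0001
GENE0121	Disease 0020
GENE0121	Disease 0027
GENE0123	Disease 0016
GENE0124	Disease 0026
GENE0127	Disease 0011
GENE0132	Disease 0003
GENE0133	Disease 0015
GENE0135	Disease 0036
GENE0137	Disease 0017
GENE0140	Disease 0035
GENE0143	Disease 0010
GENE0146	Disease 0025
GENE0147	Disease 0015
GENE0148	Disease 0009
GENE0148	Disease 0017
GENE0154	Disease 0038
GENE0156	Disease 0017
GENE0159	Disease 0020
GENE0159	Disease 0033
GENE0162	Disease 0031
GENE0163	Disease 0018
GENE0167	Disease 0017
GENE0169	Disease 0006
GENE0170	Disease 0029
GENE0170	Disease 0032
GENE0170	Disease 0033
GENE0171	Disease 0001
GENE0171	Disease 0038
GENE0175	Disease 0023
GENE0175	Disease 0033
GENE0180	Disease 0010
GENE0181	Disease 0005
GENE0181	Disease 0029
GENE0189	Disease 0001
GENE0190	Disease 0019
GENE0195	Disease 0030
GENE0196	Disease 0020
GENE0197	Disease 0002
GENE0199	Disease 0016
GENE0203	Disease 0020
GENE0208	Disease 0029
GENE0213	Disease 0018
GENE0215	Disease 0011
GENE0217	Disease 0028
GENE0218	Disease 0017
GENE0222	Disease 0005
GENE0225	Disease 0001
GENE0228	Disease 0004
GENE0228	Disease 0022
GENE0230	Disease 0035
GENE0231	Disease 0001
GENE0232	Disease 0037
GENE0236	Disease 0023
GENE0238	Disease 0001
GENE0238	Disease 0005
GENE0244	Disease 0029
GENE0246	Disease 0027
GENE0247	Disease 0009
GENE0248	Disease 0009
GENE0252	Disease 0012
GENE0252	Disease 0029
GENE0256	Disease 0010
GENE0257	Disease 0039
GENE0260	Disease 0030
GENE0265	Disease 0001
GENE0269	Disease 0021
GENE0269	Disease 0031
GENE0270	Disease 0010
GENE0274	Disease 0001
GENE0276	Disease 0012
GENE0278	Disease 0040
GENE0283	Disease 0001
GENE0283	Disease 0006
GENE0284	Disease 0020
GENE0284	Disease 0034
GENE0284	Disease 0036
GENE0289	Disease 0003
GENE0289	Disease 0005
GENE0290	Disease 0022
GENE0290	Disease 0035
GENE0291	Disease 0008
GENE0293	Disease 0001
GENE0294	Disease 0040
GENE0295	Disease 0001
GENE0295	Disease 0035
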