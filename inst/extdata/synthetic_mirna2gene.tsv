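miRNA	gene
hsa-miR-0001-5p	GENE0117
hsa-miR-0002-3p	GENE0135
hsa-miR-0002-3p	GENE0153
hsa-miR-0002-3p	GENE0173
hsa-miR-0003-5p	GENE0012
hsa-miR-0003-5p	GENE0212
hsa-miR-0004-3p	GENE0063
hsa-miR-0004-3p	GENE0121
hsa-miR-0004-3p	GENE0140
hsa-miR-0004-3p	GENE0169
hsa-miR-0005-5p	GENE0131
hsa-miR-0005-5p	GENE0141
hsa-miR-0005-5p	GENE0188
hsa-miR-0005-5p	GENE0218
hsa-miR-0006-3p	GENE0051
hsa-miR-0006-3p	GENE0194
hsa-miR-0006-3p	GENE0254
hsa-miR-0007-5p	GENE0297
hsa-miR-0008-3p	GENE0230
hsa-miR-0009-5p	GENE0240
hsa-miR-0010-3p	GENE0158
hsa-miR-0011-5p	GENE0001
hsa-miR-0013-5p	GENE0067
hsa-miR-0013-5p	GENE0217
hsa-miR-0014-3p	GENE0017
hsa-miR-0014-3p	GENE0079
hsa-miR-0014-3p	GENE0290
hsa-miR-0015-5p	GENE0151
hsa-miR-0015-5p	GENE0152
hsa-miR-0015-5p	GENE0196
hsa-miR-0016-3p	GENE0004
hsa-miR-0016-3p	GENE0037
hsa-miR-0016-3p	GENE0040
hsa-miR-0017-5p	GENE0061
hsa-miR-0017-5p	GENE0088
hsa-miR-0017-5p	GENE0135
hsa-miR-0017-5p	GENE0205
hsa-miR-0017-5p	GENE0285
hsa-miR-0018-3p	GENE0001
hsa-miR-0018-3p	GENE0027
hsa-miR-0018-3p	GENE0054
hsa-miR-0018-3p	GENE0125
hsa-miR-0018-3p	GENE0203
hsa-miR-0018-3p	GENE0278
hsa-miR-0019-5p	GENE0067
hsa-miR-0019-5p	GENE0076
hsa-miR-0020-3p	GENE0151
hsa-miR-0020-3p	GENE0250
hsa-miR-0021-5p	GENE0034
hsa-miR-0021-5p	GENE0060
hsa-miR-0021-5p	GENE0079
hsa-miR-0022-3p	GENE0120
hsa-miR-0023-5p	GENE0024
hsa-miR-0023-5p	GENE0238
hsa-miR-0023-5p	GENE0274
hsa-miR-0024-3p	GENE0158
hsa-miR-0024-3p	GENE0267
hsa-miR-0025-5p	GENE0105
hsa-miR-0026-3p	GENE0049
hsa-miR-0026-3p	GENE0106
hsa-miR-0026-3p	GENE0110
hsa-miR-0026-3p	GENE0219
hsa-miR-0026-3p	GENE0223
hsa-miR-0026-3p	GENE0275
hsa-miR-0027-5p	GENE0143
hsa-miR-0027-5p	GENE0184
hsa-miR-0027-5p	GENE0241
hsa-miR-0028-3p	GENE0171
hsa-miR-0028-3p	GENE0225
hsa-miR-0028-3p	GENE0231
hsa-miR-0029-5p	GENE0001
hsa-miR-0029-5p	GENE0096
hsa-miR-0029-5p	GENE0236
hsa-miR-0029-5p	GENE0244
hsa-miR-0029-5p	GENE0258
hsa-miR-0030-3p	GENE0118
hsa-miR-0030-3p	GENE0206
hsa-miR-0030-3p	GENE0275
hsa-miR-0031-5p	GENE0042
hsa-miR-0031-5p	GENE0122
hsa-miR-0031-5p	GENE0290
hsa-miR-0032-3p	GENE0236
hsa-miR-0032-3p	GENE0277
hsa-miR-0033-5p	GENE0046
hsa-miR-0033-5p	GENE0252
hsa-miR-0033-5p	GENE0254
hsa-miR-0034-3p	GENE0073
hsa-miR-0035-5p	GENE0189
hsa-miR-0035-5p	GENE0265
hsa-miR-0035-5p	GENE0283
hsa-miR-0036-3p	GENE0089
hsa-miR-0036-3p	GENE0090
hsa-miR-0036-3p	GENE0114
hsa-miR-0037-5p	GENE0110
hsa-miR-0037-5p	GENE0225
hsa-miR-0038-3p	GENE0171
hsa-miR-0038-3p	GENE0209
hsa-miR-0038-3p	GENE0251
hsa-miR-0038-3p	GENE0281
hsa-miR-0038-3p	GENE0299
hsa-miR-0039-5p	GENE0043
hsa-miR-0039-5p	GENE0214
hsa-miR-0040-3p	GENE0031
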