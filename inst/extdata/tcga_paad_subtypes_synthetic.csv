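sample_id,subtype
TCGA-SYN-0001,basal
TCGA-SYN-0002,classical
TCGA-SYN-0003,basal
TCGA-SYN-0004,classical
TCGA-SYN-0005,basal
TCGA-SYN-0006,basal
TCGA-SYN-0007,basal
TCGA-SYN-0008,classical
TCGA-SYN-0009,basal
TCGA-SYN-0010,classical
TCGA-SYN-0011,classical
TCGA-SYN-0012,basal
TCGA-SYN-0013,basal
TCGA-SYN-0014,basal
TCGA-SYN-0015,basal
TCGA-SYN-0016,basal
TCGA-SYN-0017,classical
TCGA-SYN-0018,classical
TCGA-SYN-0019,basal
TCGA-SYN-0020,basal
TCGA-SYN-0021,basal
TCGA-SYN-0022,basal
TCGA-SYN-0023,basal
TCGA-SYN-0024,basal
TCGA-SYN-0025,classical
TCGA-SYN-0026,classical
TCGA-SYN-0027,basal
TCGA-SYN-0028,basal
TCGA-SYN-0029,classical
TCGA-SYN-0030,basal
TCGA-SYN-0031,basal
TCGA-SYN-0032,basal
TCGA-SYN-0033,basal
TCGA-SYN-0034,basal
TCGA-SYN-0035,basal
TCGA-SYN-0036,basal
TCGA-SYN-0037,basal
TCGA-SYN-0038,basal
TCGA-SYN-0039,basal
TCGA-SYN-0040,basal
TCGA-SYN-0041,basal
TCGA-SYN-0042,classical
TCGA-SYN-0043,basal
TCGA-SYN-0044,classical
TCGA-SYN-0045,basal
TCGA-SYN-0046,basal
TCGA-SYN-0047,basal
TCGA-SYN-0048,basal
TCGA-SYN-0049,basal
TCGA-SYN-0050,basal
TCGA-SYN-0051,classical
TCGA-SYN-0052,classical
TCGA-SYN-0053,basal
TCGA-SYN-0054,classical
TCGA-SYN-0055,classical
TCGA-SYN-0056,basal
TCGA-SYN-0057,classical
TCGA-SYN-0058,classical
TCGA-SYN-0059,classical
TCGA-SYN-0060,basal
TCGA-SYN-0061,classical
TCGA-SYN-0062,basal
TCGA-SYN-0063,basal
TCGA-SYN-0064,basal
TCGA-SYN-0065,basal
TCGA-SYN-0066,classical
TCGA-SYN-0067,classical
TCGA-SYN-0068,classical
TCGA-SYN-0069,basal
TCGA-SYN-0070,basal
TCGA-SYN-0071,classical
TCGA-SYN-0072,basal
TCGA-SYN-0073,basal
TCGA-SYN-0074,basal
TCGA-SYN-0075,basal
TCGA-SYN-0076,classical
TCGA-SYN-0077,basal
TCGA-SYN-0078,basal
TCGA-SYN-0079,basal
TCGA-SYN-0080,classical
TCGA-SYN-0081,basal
TCGA-SYN-0082,classical
TCGA-SYN-0083,classical
TCGA-SYN-0084,basal
TCGA-SYN-0085,classical
TCGA-SYN-0086,classical
TCGA-SYN-0087,classical
TCGA-SYN-0088,classical
TCGA-SYN-0089,basal
TCGA-SYN-0090,classical
TCGA-SYN-0091,basal
TCGA-SYN-0092,classical
TCGA-SYN-0093,classical
TCGA-SYN-0094,classical
TCGA-SYN-0095,basal
TCGA-SYN-0096,basal
TCGA-SYN-0097,classical
TCGA-SYN-0098,basal
TCGA-SYN-0099,basal
TCGA-SYN-0100,classical
TCGA-SYN-0101,classical
TCGA-SYN-0102,basal
TCGA-SYN-0103,basal
TCGA-SYN-0104,classical
TCGA-SYN-0105,basal
TCGA-SYN-0106,basal
TCGA-SYN-0107,classical
TCGA-SYN-0108,basal
TCGA-SYN-0109,basal
TCGA-SYN-0110,classical
TCGA-SYN-0111,basal
TCGA-SYN-0112,classical
TCGA-SYN-0113,basal
TCGA-SYN-0114,classical
TCGA-SYN-0115,basal
TCGA-SYN-0116,classical
TCGA-SYN-0117,basal
TCGA-SYN-0118,basal
TCGA-SYN-0119,basal
TCGA-SYN-0120,basal
TCGA-SYN-0121,classical
TCGA-SYN-0122,classical
TCGA-SYN-0123,basal
TCGA-SYN-0124,basal
TCGA-SYN-0125,basal
TCGA-SYN-0126,basal
TCGA-SYN-0127,basal
TCGA-SYN-0128,basal
TCGA-SYN-0129,classical
TCGA-SYN-0130,classical
TCGA-SYN-0131,basal
TCGA-SYN-0132,classical
TCGA-SYN-0133,classical
TCGA-SYN-0134,classical
TCGA-SYN-0135,classical
TCGA-SYN-0136,basal
TCGA-SYN-0137,basal
TCGA-SYN-0138,classical
TCGA-SYN-0139,basal
TCGA-SYN-0140,basal
TCGA-SYN-0141,basal
TCGA-SYN-0142,basal
TCGA-SYN-0143,basal
TCGA-SYN-0144,classical
TCGA-SYN-0145,classical
TCGA-SYN-0146,classical
TCGA-SYN-0147,basal
TCGA-SYN-0148,basal
TCGA-SYN-0149,classical
TCGA-SYN-0150,classical
TCGA-SYN-0151,classical
TCGA-SYN-0152,basal
TCGA-SYN-0153,basal
TCGA-SYN-0154,classical
TCGA-SYN-0155,basal
TCGA-SYN-0156,basal
TCGA-SYN-0157,classical
TCGA-SYN-0158,basal
TCGA-SYN-0159,basal
TCGA-SYN-0160,classical
TCGA-SYN-0161,classical
TCGA-SYN-0162,basal
TCGA-SYN-0163,classical
TCGA-SYN-0164,classical
TCGA-SYN-0165,basal
TCGA-SYN-0166,basal
TCGA-SYN-0167,basal
TCGA-SYN-0168,basal
TCGA-SYN-0169,classical
TCGA-SYN-0170,basal
TCGA-SYN-0171,basal
TCGA-SYN-0172,classical
TCGA-SYN-0173,classical
TCGA-SYN-0174,classical
TCGA-SYN-0175,basal
TCGA-SYN-0176,classical
TCGA-SYN-0177,basal
TCGA-SYN-0178,basal
TCGA-SYN-0179,classical
TCGA-SYN-0180,basal
TCGA-SYN-0181,basal
TCGA-SYN-0182,basal
TCGA-SYN-0183,classical
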