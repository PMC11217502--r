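genotype,trait,s1,s2,s3,avg
Dh 86,IOD15F,0.69,0.76,0.71,0.72
Dh 86,IOD21F,0.57,0.68,0.64,0.63
Dh 86,IOD15L,0.33,0.7,0.32,0.45
Dh 86,IOD21L,0.31,0.43,0.3,0.35
Girnar 3,IOD15F,0.93,0.88,0.72,0.84
Girnar 3,IOD21F,0.84,0.64,0.56,0.68
Girnar 3,IOD15L,0.94,0.96,0.88,0.93
Girnar 3,IOD21L,0.91,0.87,0.88,0.89
PBS 15044,IOD15F,0.98,1.0,0.99,0.99
PBS 15044,IOD21F,0.98,0.98,0.99,0.98
PBS 15044,IOD15L,0.98,0.97,0.96,0.97
PBS 15044,IOD21L,0.91,0.92,0.89,0.91
PBS 16004,IOD15F,0.99,1.0,1.0,1.0
PBS 16004,IOD21F,0.97,0.98,1.0,0.98
PBS 16004,IOD15L,1.0,1.0,1.0,1.0
PBS 16004,IOD21L,0.96,0.98,1.0,0.98
PBS 16013,IOD15F,0.98,1.0,1.0,0.99
PBS 16013,IOD21F,0.98,1.0,1.0,0.99
PBS 16013,IOD15L,1.0,1.0,0.93,0.98
PBS 16013,IOD21L,0.97,0.93,0.93,0.94
PBS 16015,IOD15F,1.0,1.0,1.0,1.0
PBS 16015,IOD21F,1.0,1.0,1.0,1.0
PBS 16015,IOD15L,1.0,1.0,1.0,1.0
PBS 16015,IOD21L,1.0,1.0,1.0,1.0
PBS 16016,IOD15F,0.99,1.0,0.99,0.99
PBS 16016,IOD21F,0.99,0.99,0.99,0.99
PBS 16016,IOD15L,1.0,1.0,1.0,1.0
PBS 16016,IOD21L,1.0,1.0,1.0,1.0
PBS 16017,IOD15F,1.0,0.99,0.99,0.99
PBS 16017,IOD21F,0.97,0.94,0.97,0.96
PBS 16017,IOD15L,1.0,0.99,1.0,1.0
PBS 16017,IOD21L,0.99,0.97,1.0,0.99
PBS 16020,IOD15F,0.98,1.0,1.0,0.99
PBS 16020,IOD21F,0.95,0.93,1.0,0.96
PBS 16020,IOD15L,0.97,0.97,0.97,0.97
PBS 16020,IOD21L,0.93,0.9,0.97,0.93
PBS 16021,IOD15F,1.0,1.0,1.0,1.0
PBS 16021,IOD21F,0.98,1.0,1.0,0.99
PBS 16021,IOD15L,1.0,1.0,1.0,1.0
PBS 16021,IOD21L,0.99,1.0,1.0,1.0
PBS 16024,IOD15F,0.58,0.87,0.87,0.77
PBS 16024,IOD21F,0.5,0.81,0.79,0.7
PBS 16024,IOD15L,0.63,0.86,0.71,0.73
PBS 16024,IOD21L,0.61,0.6,0.71,0.64
PBS 16025,IOD15F,0.43,0.21,0.13,0.26
PBS 16025,IOD21F,0.35,0.07,0.04,0.15
PBS 16025,IOD15L,0.2,0.4,0.11,0.24
PBS 16025,IOD21L,0.04,0.21,0.0,0.09
PBS 16026,IOD15F,0.98,0.99,0.98,0.98
PBS 16026,IOD21F,0.95,0.96,0.98,0.96
PBS 16026,IOD15L,0.97,1.0,1.0,0.99
PBS 16026,IOD21L,0.96,1.0,1.0,0.99
PBS 16027,IOD15F,0.45,0.23,0.26,0.31
PBS 16027,IOD21F,0.32,0.14,0.1,0.19
PBS 16027,IOD15L,0.24,0.28,0.08,0.2
PBS 16027,IOD21L,0.04,0.04,0.0,0.03
PBS 16028,IOD15F,0.19,0.06,0.0,0.08
PBS 16028,IOD21F,0.0,0.0,0.0,0.0
PBS 16028,IOD15L,0.21,0.24,0.1,0.19
PBS 16028,IOD21L,0.09,0.08,0.02,0.06
PBS 16029,IOD15F,0.47,0.14,0.07,0.23
PBS 16029,IOD21F,0.18,0.11,0.0,0.1
PBS 16029,IOD15L,0.22,0.3,0.06,0.19
PBS 16029,IOD21L,0.09,0.0,0.0,0.03
PBS 16031,IOD15F,0.96,1.0,1.0,0.99
PBS 16031,IOD21F,0.96,0.97,1.0,0.98
PBS 16031,IOD15L,1.0,1.0,1.0,1.0
PBS 16031,IOD21L,0.98,1.0,1.0,0.99
PBS 16032,IOD15F,0.29,0.56,0.3,0.38
PBS 16032,IOD21F,0.04,0.24,0.18,0.15
PBS 16032,IOD15L,0.26,0.52,0.07,0.28
PBS 16032,IOD21L,0.04,0.03,0.0,0.03
PBS 16035,IOD15F,0.98,0.97,0.94,0.96
PBS 16035,IOD21F,0.98,0.92,0.91,0.94
PBS 16035,IOD15L,0.99,0.97,1.0,0.99
PBS 16035,IOD21L,0.98,0.88,1.0,0.95
PBS 16037,IOD15F,0.98,1.0,1.0,0.99
PBS 16037,IOD21F,0.97,0.96,1.0,0.97
PBS 16037,IOD15L,1.0,1.0,1.0,1.0
PBS 16037,IOD21L,0.97,0.96,1.0,0.97
PBS 16038,IOD15F,0.97,1.0,1.0,0.99
PBS 16038,IOD21F,0.93,1.0,1.0,0.98
PBS 16038,IOD15L,0.97,1.0,0.97,0.98
PBS 16038,IOD21L,0.94,0.99,0.97,0.97
PBS 16039,IOD15F,0.95,1.0,1.0,0.98
PBS 16039,IOD21F,0.8,0.96,1.0,0.92
PBS 16039,IOD15L,1.0,0.93,1.0,0.98
PBS 16039,IOD21L,0.94,0.88,1.0,0.94
PBS 16041,IOD15F,1.0,1.0,1.0,1.0
PBS 16041,IOD21F,1.0,1.0,1.0,1.0
PBS 16041,IOD15L,1.0,1.0,1.0,1.0
PBS 16041,IOD21L,1.0,1.0,1.0,1.0
PBS 16042,IOD15F,0.93,0.96,0.91,0.93
PBS 16042,IOD21F,0.85,0.88,0.9,0.88
PBS 16042,IOD15L,0.97,1.0,0.97,0.98
PBS 16042,IOD21L,0.92,0.93,0.93,0.93
PBS 16044,IOD15F,0.22,0.11,0.01,0.11
PBS 16044,IOD21F,0.08,0.0,0.0,0.03
PBS 16044,IOD15L,0.21,0.03,0.14,0.13
PBS 16044,IOD21L,0.04,0.0,0.09,0.04
PBS 16045,IOD15F,1.0,1.0,1.0,1.0
PBS 16045,IOD21F,1.0,0.99,1.0,1.0
PBS 16045,IOD15L,1.0,1.0,0.97,0.99
PBS 16045,IOD21L,0.97,0.93,0.97,0.96
PBS 16046,IOD15F,0.79,0.89,0.89,0.86
PBS 16046,IOD21F,0.75,0.6,0.8,0.72
PBS 16046,IOD15L,0.42,0.77,0.7,0.63
PBS 16046,IOD21L,0.26,0.63,0.62,0.5
PBS 16047,IOD15F,0.77,0.22,0.2,0.4
PBS 16047,IOD21F,0.6,0.11,0.11,0.28
PBS 16047,IOD15L,0.31,0.28,0.39,0.33
PBS 16047,IOD21L,0.04,0.26,0.26,0.19
PBS 16051,IOD15F,0.64,0.37,0.39,0.46
PBS 16051,IOD21F,0.53,0.14,0.24,0.31
PBS 16051,IOD15L,0.37,0.77,0.23,0.46
PBS 16051,IOD21L,0.18,0.46,0.12,0.25
PBS 16052,IOD15F,0.89,0.16,0.1,0.38
PBS 16052,IOD21F,0.6,0.03,0.03,0.22
PBS 16052,IOD15L,0.7,0.29,0.27,0.42
PBS 16052,IOD21L,0.3,0.11,0.1,0.17
PBS 16053,IOD15F,1.0,0.89,0.76,0.88
PBS 16053,IOD21F,0.99,0.74,0.67,0.8
PBS 16053,IOD15L,0.79,0.8,0.6,0.73
PBS 16053,IOD21L,0.62,0.5,0.32,0.48
TPG 41,IOD15F,0.93,0.97,0.96,0.95
TPG 41,IOD21F,0.92,0.92,0.96,0.93
TPG 41,IOD15L,0.99,0.92,0.94,0.95
TPG 41,IOD21L,0.91,0.88,0.91,0.9
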