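genotype,trait,s1,s2,s3,avg
Dh 86,PYLP,0.57,0.57,0.3,0.48
Dh 86,HPW,0.61,0.61,0.48,0.57
Dh 86,HKW,0.82,0.53,0.57,0.64
Dh 86,SP,0.96,0.95,0.97,0.96
Girnar 3,PYLP,0.68,0.54,0.6,0.6
Girnar 3,HPW,0.64,0.7,0.64,0.66
Girnar 3,HKW,0.88,0.48,0.9,0.75
Girnar 3,SP,0.82,0.83,0.87,0.84
PBS 15044,PYLP,0.81,0.75,0.6,0.72
PBS 15044,HPW,0.92,0.93,0.87,0.91
PBS 15044,HKW,0.86,0.76,0.8,0.81
PBS 15044,SP,0.86,0.85,0.91,0.87
PBS 16004,PYLP,0.85,0.88,0.55,0.76
PBS 16004,HPW,0.91,0.85,0.8,0.85
PBS 16004,HKW,0.79,0.66,0.67,0.7
PBS 16004,SP,0.74,0.85,0.87,0.82
PBS 16013,PYLP,0.7,0.66,0.72,0.69
PBS 16013,HPW,0.74,0.79,0.67,0.73
PBS 16013,HKW,0.8,0.65,0.59,0.68
PBS 16013,SP,0.86,0.96,1.0,0.94
PBS 16015,PYLP,0.8,0.8,0.35,0.65
PBS 16015,HPW,0.88,0.92,0.62,0.81
PBS 16015,HKW,0.87,0.74,0.69,0.77
PBS 16015,SP,0.84,0.91,0.9,0.88
PBS 16016,PYLP,0.57,0.6,0.43,0.53
PBS 16016,HPW,0.78,0.75,0.48,0.67
PBS 16016,HKW,1.0,0.8,0.81,0.87
PBS 16016,SP,0.75,0.83,0.75,0.77
PBS 16017,PYLP,0.4,0.45,0.37,0.41
PBS 16017,HPW,0.73,0.66,0.62,0.67
PBS 16017,HKW,0.67,0.61,0.56,0.61
PBS 16017,SP,0.73,0.83,0.75,0.77
PBS 16020,PYLP,0.64,0.69,0.72,0.68
PBS 16020,HPW,0.93,0.88,0.81,0.87
PBS 16020,HKW,0.85,0.73,0.63,0.74
PBS 16020,SP,0.87,0.9,0.99,0.92
PBS 16021,PYLP,0.67,0.7,0.45,0.61
PBS 16021,HPW,0.99,1.0,0.87,0.95
PBS 16021,HKW,0.9,0.7,0.8,0.8
PBS 16021,SP,0.62,0.63,0.78,0.68
PBS 16024,PYLP,0.39,0.46,0.52,0.46
PBS 16024,HPW,0.93,0.88,0.51,0.77
PBS 16024,HKW,0.64,0.6,0.47,0.57
PBS 16024,SP,0.62,0.74,0.91,0.75
PBS 16025,PYLP,0.83,0.77,0.72,0.77
PBS 16025,HPW,0.89,0.85,0.79,0.84
PBS 16025,HKW,0.8,0.69,0.68,0.73
PBS 16025,SP,0.8,0.81,0.86,0.82
PBS 16026,PYLP,0.58,0.62,0.78,0.66
PBS 16026,HPW,0.69,0.54,0.45,0.56
PBS 16026,HKW,0.65,0.57,0.5,0.57
PBS 16026,SP,0.6,0.65,0.59,0.62
PBS 16027,PYLP,0.89,0.88,0.57,0.78
PBS 16027,HPW,0.7,0.69,0.57,0.65
PBS 16027,HKW,0.78,0.62,0.61,0.67
PBS 16027,SP,0.91,0.93,0.93,0.92
PBS 16028,PYLP,0.98,0.88,0.83,0.89
PBS 16028,HPW,0.77,0.77,0.61,0.72
PBS 16028,HKW,0.57,0.6,0.49,0.55
PBS 16028,SP,0.9,0.93,0.96,0.93
PBS 16029,PYLP,0.54,0.73,0.67,0.64
PBS 16029,HPW,0.72,0.68,0.57,0.65
PBS 16029,HKW,0.63,0.58,0.62,0.61
PBS 16029,SP,0.91,0.94,0.93,0.93
PBS 16031,PYLP,0.65,0.74,0.82,0.74
PBS 16031,HPW,0.62,0.59,0.61,0.6
PBS 16031,HKW,0.63,0.54,0.51,0.56
PBS 16031,SP,0.89,0.95,0.96,0.93
PBS 16032,PYLP,1.0,1.0,0.59,0.86
PBS 16032,HPW,0.94,0.96,1.0,0.97
PBS 16032,HKW,0.95,0.95,1.0,0.97
PBS 16032,SP,0.98,1.0,0.96,0.98
PBS 16035,PYLP,0.55,0.72,0.56,0.61
PBS 16035,HPW,0.92,0.86,0.79,0.86
PBS 16035,HKW,0.75,0.65,0.67,0.69
PBS 16035,SP,0.77,0.82,0.83,0.81
PBS 16037,PYLP,0.51,0.78,0.44,0.57
PBS 16037,HPW,0.77,0.77,0.77,0.77
PBS 16037,HKW,0.85,0.82,0.73,0.8
PBS 16037,SP,0.7,0.72,0.82,0.75
PBS 16038,PYLP,0.4,0.62,0.44,0.49
PBS 16038,HPW,0.91,0.94,0.81,0.88
PBS 16038,HKW,0.86,1.0,0.72,0.86
PBS 16038,SP,1.0,0.98,1.0,0.99
PBS 16039,PYLP,0.41,0.66,0.6,0.56
PBS 16039,HPW,1.0,0.91,0.83,0.92
PBS 16039,HKW,0.88,0.93,0.87,0.89
PBS 16039,SP,0.84,0.94,0.95,0.91
PBS 16041,PYLP,0.49,0.68,0.62,0.6
PBS 16041,HPW,0.56,0.63,0.58,0.59
PBS 16041,HKW,0.69,0.56,0.5,0.58
PBS 16041,SP,0.8,0.9,0.96,0.89
PBS 16042,PYLP,0.38,0.61,0.7,0.56
PBS 16042,HPW,0.8,0.59,0.55,0.65
PBS 16042,HKW,0.72,0.56,0.59,0.62
PBS 16042,SP,0.69,0.76,0.8,0.75
PBS 16044,PYLP,0.59,0.78,0.44,0.6
PBS 16044,HPW,0.61,0.62,0.58,0.6
PBS 16044,HKW,0.64,0.57,0.52,0.57
PBS 16044,SP,0.81,0.92,0.87,0.86
PBS 16045,PYLP,0.44,0.64,0.54,0.54
PBS 16045,HPW,0.76,0.7,0.67,0.71
PBS 16045,HKW,0.74,0.66,0.61,0.67
PBS 16045,SP,0.77,0.85,0.93,0.85
PBS 16046,PYLP,0.62,0.76,1.0,0.79
PBS 16046,HPW,0.9,0.87,0.85,0.87
PBS 16046,HKW,0.79,0.66,0.66,0.7
PBS 16046,SP,0.67,0.82,0.83,0.77
PBS 16047,PYLP,0.62,0.68,0.35,0.55
PBS 16047,HPW,0.92,0.79,0.85,0.85
PBS 16047,HKW,0.71,0.62,0.62,0.65
PBS 16047,SP,0.78,0.89,0.9,0.86
PBS 16051,PYLP,0.44,0.49,0.32,0.41
PBS 16051,HPW,0.62,0.63,0.66,0.63
PBS 16051,HKW,0.61,0.59,0.44,0.55
PBS 16051,SP,0.9,0.87,0.63,0.8
PBS 16052,PYLP,0.75,0.83,0.54,0.71
PBS 16052,HPW,0.69,0.71,0.76,0.72
PBS 16052,HKW,0.57,0.56,0.57,0.56
PBS 16052,SP,0.67,0.7,0.81,0.73
PBS 16053,PYLP,0.85,0.98,0.57,0.8
PBS 16053,HPW,0.9,0.89,0.7,0.83
PBS 16053,HKW,0.85,0.79,0.76,0.8
PBS 16053,SP,0.87,0.74,0.77,0.79
TPG 41,PYLP,0.7,0.63,0.88,0.74
TPG 41,HPW,0.71,0.74,0.55,0.67
TPG 41,HKW,0.76,0.61,0.66,0.68
TPG 41,SP,0.81,0.79,0.6,0.73
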