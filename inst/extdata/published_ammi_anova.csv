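trait,source,df,MS,pctSS
IOD15F,ENV,2,1868.30,1.19
IOD15F,REP(ENV),6,83.80,0.16
IOD15F,GEN,31,8931.10,88.36
IOD15F,ENV:GEN,62,432.50,8.56
IOD15F,PC1,32,788.36,94.10
IOD15F,PC2,30,52.88,5.90
IOD15F,Residuals,186,29.10,1.73
IOD21F,ENV,2,948.30,0.48
IOD21F,REP(ENV),6,73.20,0.11
IOD21F,GEN,31,11748.50,91.71
IOD21F,ENV:GEN,62,359.90,5.62
IOD21F,PC1,32,652.33,93.60
IOD21F,PC2,30,47.95,6.40
IOD21F,Residuals,186,44.40,2.08
IOD15L,ENV,2,1558.70,0.93
IOD15L,REP(ENV),6,187.40,0.34
IOD15L,GEN,31,9633.30,89.54
IOD15L,ENV:GEN,62,305.60,5.68
IOD15L,PC1,32,401.76,67.90
IOD15L,PC2,30,203.00,32.10
IOD15L,Residuals,186,62.90,3.51
IOD21L,ENV,2,56.60,0.02
IOD21L,REP(ENV),6,184.10,0.24
IOD21L,GEN,31,13860.30,94.46
IOD21L,ENV:GEN,62,163.30,2.23
IOD21L,PC1,32,191.50,60.5
IOD21L,PC2,30,133.31,39.5
IOD21L,Residuals,186,74.50,3.05
PYLP,ENV,2,487.43,46.00
PYLP,REP(ENV),6,1.25,0.36
PYLP,GEN,31,14.59,21.34
PYLP,ENV:GEN,62,5.75,16.81
PYLP,PC1,32,9.73,87.40
PYLP,PC2,30,1.50,12.60
PYLP,Residuals,186,1.76,15.49
HPW,ENV,2,7173.00,19.38
HPW,REP(ENV),6,190.20,1.54
HPW,GEN,31,1320.30,55.29
HPW,ENV:GEN,62,145.20,12.16
HPW,PC1,32,217.79,77.40
HPW,PC2,30,67.86,22.60
HPW,Residuals,186,46.30,11.63
HKW,ENV,2,798.75,9.02
HKW,REP(ENV),6,61.89,2.10
HKW,GEN,31,305.29,53.41
HKW,ENV:GEN,62,41.41,14.49
HKW,PC1,32,54.70,68.20
HKW,PC2,30,27.24,31.80
HKW,Residuals,186,20.00,20.99
SP,ENV,2,5036.40,35.45
SP,REP(ENV),6,91.70,1.94
SP,GEN,31,352.30,38.44
SP,ENV:GEN,62,52.00,11.34
SP,PC1,32,83.01,82.40
SP,PC2,30,18.85,17.60
SP,Residuals,186,19.60,12.83
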