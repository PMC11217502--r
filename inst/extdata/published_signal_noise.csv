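trait,signal_SS,pct_signal,noise_SS,pct_noise
IOD15F,25009.80,93.27,1804.20,6.73
IOD21F,19560.20,87.66,2752.80,12.34
IOD15L,15046.20,79.42,3899.80,20.58
IOD21L,5508.00,54.39,4619.00,45.61
PYLP,247.12,69.37,109.12,30.63
HPW,6134.40,68.12,2870.60,31.88
HKW,1327.50,51.70,1240.00,48.30
SP,2006.60,62.28,1215.20,37.72
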