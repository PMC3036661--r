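signal,alignment,beats,percent_nondet,e_det,e_total,e_nondet,total_rounded
Pre-recorded PCG 1,none,all,73.20,266.42,994.00,727.59,FALSE
Pre-recorded PCG 1,S1,all,35.18,624.23,962.98,338.76,FALSE
Pre-recorded PCG 1,S1,removed,33.11,656.68,981.71,325.03,FALSE
Pre-recorded PCG 1,S2,all,29.87,691.23,985.57,294.35,FALSE
Pre-recorded PCG 2,none,all,88.17,106.21,898.09,791.88,FALSE
Pre-recorded PCG 2,S1,all,6.82,836.76,897.99,61.23,FALSE
Pre-recorded PCG 2,S1,removed,6.87,816.82,877.10,60.27,FALSE
Pre-recorded PCG 2,S2,all,6.16,842.66,897.96,55.29,FALSE
Pre-recorded PCG 3,none,all,71.59,432.08,1520,1090,TRUE
Pre-recorded PCG 3,S1,all,47.81,781.33,1500,715.65,TRUE
Pre-recorded PCG 3,S1,removed,44.60,843.53,1520,678.99,TRUE
Pre-recorded PCG 3,S2,all,63.47,544.78,1490,946.43,TRUE
Karim stethoscope signal 1,none,all,51.29,229.67,471.52,241.85,FALSE
Karim stethoscope signal 1,S1,all,48.40,225.76,437.49,211.73,FALSE
Karim stethoscope signal 1,S1,removed,41.86,273.14,469.80,196.66,FALSE
Karim stethoscope signal 1,S2,all,77.49,96.72,429.71,332.98,FALSE
MHV Recording 1,none,all,95.74,25.31,593.73,568.42,FALSE
MHV Recording 1,S1,all,77.81,130.89,589.89,458.99,FALSE
MHV Recording 1,S1,removed,73.56,156.91,593.44,436.53,FALSE
MHV Recording 1,S2,all,93.21,32.05,472.10,440.05,FALSE
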