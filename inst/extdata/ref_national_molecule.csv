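molecule,ddds_million,ddd_share_pct,cost_billion,cost_share_pct,cost_per_ddd
ceftriaxone,88.1,33.6,11.6,15.3,131.3
amikacin,35.3,13.5,7.3,9.7,207.3
gentamicin,22.8,8.7,0.6612,0.87,29.0
ceftriaxone+sulbactam,17.2,6.6,5.7,7.5,330.7
cefotaxime,13.8,5.3,2.5,3.2,177.6
All the other antibiotics,85.3,32.4,48.0,63.4,1705.5
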