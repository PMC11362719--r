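group,atc4,ddds_million,ddd_share_pct,cost_billion,cost_share_pct,cost_per_ddd
Third generation cephalosporins,J01DD,139.7,53.2,32.0,42.3,229.2
Other aminoglycosides,J01GB,59.6,22.7,8.4,11.2,141.6
"Combinations of penicillin, incl. BLIs",J01CR,24.1,9.2,9.3,12.3,386.1
Lincosamides,J01FF,8.8,3.3,1.5,2.0,173.2
Fluoroquinolones,J01MA,8.5,3.2,1.8,2.4,213.6
All the other groups,,21.9,8.3,22.6,29.9,1662.8
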