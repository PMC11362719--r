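group,atc3,ddds_million,ddd_share_pct,cost_billion,cost_share_pct,cost_per_ddd
Other beta-lactam antibacterials,J01D,145.8,55.5,45.7,60.4,313.8
Aminoglycoside antibacterials,J01G,59.6,22.7,8.4,11.2,141.7
"Beta-lactam antibacterials, penicillin",J01C,29.3,11.2,9.6,12.7,328.3
"Macrolides, lincosamides and streptogramins",J01F,9.5,3.6,1.7,2.3,182.9
Quinolone antibacterials,J01M,8.5,3.2,1.8,2.4,213.6
All the other groups,,9.9,3.8,8.3,1.0,1194.5
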