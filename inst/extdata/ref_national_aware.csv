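aware,ddds_million,ddd_share_pct,cost_billion,cost_share_pct,cost_per_ddd
Access,69.5,26.5,11.6,15.4,167.5
Watch,133.7,50.9,39.6,52.3,296.2
Reserve,1.6,0.61,4.5,5.9,2798.8
Discouraged,57.7,21.9,19.9,26.3,345.0
NotListed,0.01852,0.01,0.0361,0.05,1951.8
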