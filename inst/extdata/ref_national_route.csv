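route,ddds_million,ddd_share_pct,cost_billion,cost_share_pct,per_capita_cost,cost_per_ddd
injectable,262.6,5.1,75.7,35.8,57.7,288.2
oral,4860.9,94.9,135.9,64.2,103.5,27.9
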