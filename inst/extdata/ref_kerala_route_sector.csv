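route,public_ddds_million,private_ddds_million,public_cost_million,private_cost_million
oral,110.4,167.2,500.6,4909.5
injectable,2.6,5.5,167.4,2505.3
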