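aware,public_ddds_million,private_ddds_million,public_did,private_did
Access,0.63,1.2,0.049,0.096
Watch,1.6,3.3,0.129,0.259
Reserve,0.02,0.07,0.002,0.005
Discouraged,0.26,1.0,0.021,0.079
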