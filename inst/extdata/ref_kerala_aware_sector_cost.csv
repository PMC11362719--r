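aware,public_cost_million,private_cost_million
Access,27.4,266.7
Watch,111.0,1493.1
Reserve,4.0,163.0
Discouraged,25.0,582.5
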