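molecule,private_ddd_thousand,public_ddd_thousand,private_cost_thousand,public_cost_thousand
amoxicillin+clavulanic acid,239.6,95.5,114490.3,8974.1
ampicillin,58.9,79.6,13160.9,5616.0
azithromycin,28.7,23.0,4873.8,1292.7
aztreonam,0.6,1.4,1905.0,2168.1
benzylpenicillin,0,161.4,0,8418.6
cefoperazone+sulbactam,186.9,264.6,392464.6,25035.1
cefotaxime,531.8,691.7,84675.9,34730.6
ceftazidime,13.5,2.1,11609.5,336.2
ceftriaxone,1754.7,475.0,224424.1,12097.3
cefuroxime,223.3,130.8,152998.8,8634.9
ciprofloxacin,77.6,94.2,6025.8,3638.3
cloxacillin,0,19.1,0,750.5
gentamicin,433.6,271.6,12327.4,3687.3
levofloxacin,140.5,13.2,22153.6,370.7
linezolid,58.7,23.8,63933.0,3317.0
meropenem,120.0,13.0,570866.8,4662.4
ofloxacin,107.8,21.3,27120.6,539.8
piperacillin+tazobactam,196.1,170.9,224435.3,42797.5
teicoplanin,33.4,1.0,78317.0,327.0
tigecycline,1.9,0.2,11584.9,237.2
vancomycin,10.1,21.7,11205.8,3222.1
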