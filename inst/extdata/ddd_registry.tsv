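molecule	atc5	route	ddd_value	ddd_unit	aware	is_fdc	components	ddd_source
amikacin	J01GB06	injectable	1	g	Access	FALSE		who_index
amoxicillin	J01CA04	injectable	3	g	Access	FALSE		who_index
amoxicillin+clavulanic acid	J01CR02	injectable	3	g	Access	TRUE	amoxicillin;clavulanic acid	who_combined
ampicillin	J01CA01	injectable	6	g	Access	FALSE		who_index
ampicillin+cloxacillin	J01CR50	injectable	4	g	Discouraged	TRUE	ampicillin;cloxacillin	principal_component
azithromycin	J01FA10	injectable	0.5	g	Watch	FALSE		who_index
aztreonam	J01DF01	injectable	4	g	Reserve	FALSE		who_index
benzylpenicillin	J01CE01	injectable	6	MU	Access	FALSE		who_index
cefepime	J01DE01	injectable	4	g	Watch	FALSE		who_index
cefoperazone	J01DD12	injectable	4	g	Watch	FALSE		who_index
cefoperazone+sulbactam	J01DD62	injectable	4	g	Watch	TRUE	cefoperazone;sulbactam	principal_component
cefotaxime	J01DD01	injectable	4	g	Watch	FALSE		who_index
ceftazidime	J01DD02	injectable	4	g	Watch	FALSE		who_index
ceftriaxone	J01DD04	injectable	2	g	Watch	FALSE		who_index
ceftriaxone+sulbactam	J01DD63	injectable	2	g	Discouraged	TRUE	ceftriaxone;sulbactam	principal_component
ceftriaxone+tazobactam	J01DD64	injectable	2	g	Discouraged	TRUE	ceftriaxone;tazobactam	principal_component
cefuroxime	J01DC02	injectable	3	g	Watch	FALSE		who_index
ciprofloxacin	J01MA02	injectable	0.8	g	Watch	FALSE		who_index
clindamycin	J01FF01	injectable	1.8	g	Access	FALSE		who_index
cloxacillin	J01CF02	injectable	2	g	Access	FALSE		who_index
colistin	J01XB01	injectable	9	MU	Reserve	FALSE		who_index
doxycycline	J01AA02	injectable	0.1	g	Access	FALSE		who_index
gentamicin	J01GB03	injectable	0.24	g	Access	FALSE		who_index
imipenem+cilastatin	J01DH51	injectable	2	g	Watch	TRUE	imipenem;cilastatin	who_combined
levofloxacin	J01MA12	injectable	0.5	g	Watch	FALSE		who_index
linezolid	J01XX08	injectable	1.2	g	Reserve	FALSE		who_index
meropenem	J01DH02	injectable	3	g	Watch	FALSE		who_index
netilmicin	J01GB07	injectable	0.35	g	Watch	FALSE		who_index
ofloxacin	J01MA01	injectable	0.4	g	Watch	FALSE		who_index
piperacillin+tazobactam	J01CR05	injectable	14	g	Watch	TRUE	piperacillin;tazobactam	who_combined
polymyxin b	J01XB02	injectable	0.15	g	Reserve	FALSE		who_index
streptomycin	J01GA01	injectable	1	g	Watch	FALSE		who_index
teicoplanin	J01XA02	injectable	0.4	g	Watch	FALSE		who_index
tigecycline	J01AA12	injectable	0.1	g	Reserve	FALSE		who_index
vancomycin	J01XA01	injectable	2	g	Watch	FALSE		who_index
amoxicillin	J01CA04	oral	1.5	g	Access	FALSE		who_index
amoxicillin+clavulanic acid	J01CR02	oral	1.5	g	Access	TRUE	amoxicillin;clavulanic acid	who_combined
ampicillin+cloxacillin	J01CR50	oral	2	g	Discouraged	TRUE	ampicillin;cloxacillin	principal_component
azithromycin	J01FA10	oral	0.3	g	Watch	FALSE		who_index
cefalexin	J01DB01	oral	2	g	Access	FALSE		who_index
cefixime	J01DD08	oral	0.4	g	Watch	FALSE		who_index
cefpodoxime	J01DD13	oral	0.4	g	Watch	FALSE		who_index
cefuroxime	J01DC02	oral	0.5	g	Watch	FALSE		who_index
ciprofloxacin	J01MA02	oral	1	g	Watch	FALSE		who_index
doxycycline	J01AA02	oral	0.1	g	Access	FALSE		who_index
levofloxacin	J01MA12	oral	0.5	g	Watch	FALSE		who_index
nitrofurantoin	J01XE01	oral	0.2	g	Access	FALSE		who_index
norfloxacin	J01MA06	oral	0.8	g	Watch	FALSE		who_index
ofloxacin	J01MA01	oral	0.4	g	Watch	FALSE		who_index
sulfamethoxazole+trimethoprim	J01EE01	oral	1.92	g	Access	TRUE	sulfamethoxazole;trimethoprim	who_combined
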