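drug_code,name,drug_class,is_booster
AZT,zidovudine,NRTI,FALSE
DDI,didanosine,NRTI,FALSE
D4T,stavudine,NRTI,FALSE
3TC,lamivudine,NRTI,FALSE
FTC,emtricitabine,NRTI,FALSE
ABC,abacavir,NRTI,FALSE
TDF,tenofovir disoproxil,NRTI,FALSE
TAF,tenofovir alafenamide,NRTI,FALSE
EFV,efavirenz,NNRTI,FALSE
NVP,nevirapine,NNRTI,FALSE
ETR,etravirine,NNRTI,FALSE
RPV,rilpivirine,NNRTI,FALSE
DOR,doravirine,NNRTI,FALSE
SQV,saquinavir,PI,FALSE
IDV,indinavir,PI,FALSE
NFV,nelfinavir,PI,FALSE
LPV,lopinavir,PI,FALSE
ATV,atazanavir,PI,FALSE
FPV,fosamprenavir,PI,FALSE
TPV,tipranavir,PI,FALSE
DRV,darunavir,PI,FALSE
RAL,raltegravir,INSTI,FALSE
EVG,elvitegravir,INSTI,FALSE
DTG,dolutegravir,INSTI,FALSE
BIC,bictegravir,INSTI,FALSE
CAB,cabotegravir,INSTI,FALSE
ENF,enfuvirtide,ENTRY,FALSE
MVC,maraviroc,ENTRY,FALSE
IBA,ibalizumab,ENTRY,FALSE
FTR,fostemsavir,ENTRY,FALSE
LEN,lenacapavir,CAPSID,FALSE
RTV,ritonavir,PI,TRUE
COBI,cobicistat,OTHER,TRUE
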