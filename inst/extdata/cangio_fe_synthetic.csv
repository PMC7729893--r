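site_id,region,compartment,metal,conc
NP1,CanGio,soil,Fe,24620
DK4,CanGio,soil,Fe,17986
DK6,CanGio,soil,Fe,26745
DK7,CanGio,soil,Fe,28454
DK8,CanGio,soil,Fe,30330
NP2,CanGio,soil,Fe,24427
DN1,ThiVai,soil,Fe,55476
DN2,ThiVai,soil,Fe,40282
M5,ThiVai,soil,Fe,34619
M3,ThiVai,soil,Fe,32943
M1,ThiVai,soil,Fe,22191
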