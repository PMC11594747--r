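# OAG group (21 eyes): regional means and standard deviations as published.
# The GCL_T Area3 mean was printed with its leading digits dropped (0.190);
# the value here (20.190) is the mean of the individual Area3 column.
region_type,region,measure,mean,sd,n,units
ring,R1,mfPhNR_RAD,15.924,5.188,21,nV_per_deg2
area,Area1,GCL_T,26.829,6.207,21,um
ring,R2,mfPhNR_RAD,6.795,2.236,21,nV_per_deg2
area,Area2,GCL_T,23.886,3.27,21,um
ring,R3+R4,mfPhNR_RAD,4.271,1.43,21,nV_per_deg2
area,Area3,GCL_T,20.19,1.663,21,um
sector,ST,mfPhNR_RAD,2.2,0.716,21,nV_per_deg2
sector,ST,GCL_T,21.029,5.288,21,um
sector,IT,mfPhNR_RAD,1.967,0.687,21,nV_per_deg2
sector,IT,GCL_T,19.776,4.104,21,um
sector,IN,mfPhNR_RAD,1.681,0.434,21,nV_per_deg2
sector,IN,GCL_T,23.19,3.793,21,um
sector,SN,mfPhNR_RAD,1.557,0.407,21,nV_per_deg2
sector,SN,GCL_T,24.067,4.996,21,um
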