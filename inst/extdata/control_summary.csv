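# Control group (20 eyes): regional means and standard deviations (n-1 denominator).
region_type,region,measure,mean,sd,n,units
ring,R1,mfPhNR_RAD,30.047,4.616,20,nV_per_deg2
area,Area1,GCL_T,45.224,3.865,20,um
ring,R2,mfPhNR_RAD,14.737,5.073,20,nV_per_deg2
area,Area2,GCL_T,33.15,2.16,20,um
ring,R3+R4,mfPhNR_RAD,7.175,0.962,20,nV_per_deg2
area,Area3,GCL_T,24.03,1.707,20,um
sector,ST,mfPhNR_RAD,5.041,1.431,20,nV_per_deg2
sector,ST,GCL_T,27.2,2.575,20,um
sector,IT,mfPhNR_RAD,5.127,1.624,20,nV_per_deg2
sector,IT,GCL_T,28.486,2.444,20,um
sector,IN,mfPhNR_RAD,5.382,1.859,20,nV_per_deg2
sector,IN,GCL_T,28.941,2.021,20,um
sector,SN,mfPhNR_RAD,5.314,1.637,20,nV_per_deg2
sector,SN,GCL_T,29.632,1.812,20,um
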