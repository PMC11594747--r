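# One-sided lower normative limits (95% confidence limits) derived from the
# 20-eye control group, as distributed with the cohort table.
region_type,region,measure,limit,units
ring,R1,mfPhNR_RAD,26.92,nV_per_deg2
area,Area1,GCL_T,43.51,um
ring,R2,mfPhNR_RAD,12.71,nV_per_deg2
area,Area2,GCL_T,32.2,um
ring,R3+R4,mfPhNR_RAD,6.72,nV_per_deg2
area,Area3,GCL_T,23.27,um
sector,ST,mfPhNR_RAD,4.41,nV_per_deg2
sector,ST,GCL_T,26.03,um
sector,IT,mfPhNR_RAD,4.41,nV_per_deg2
sector,IT,GCL_T,27.4,um
sector,IN,mfPhNR_RAD,4.56,nV_per_deg2
sector,IN,GCL_T,28.05,um
sector,SN,mfPhNR_RAD,4.59,nV_per_deg2
sector,SN,GCL_T,28.83,um
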