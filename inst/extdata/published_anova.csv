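# Published group-comparison results (one-way ANOVA F, df = (1, 39), and
# counts of OAG eyes below the normative limit) used for reconciliation.
# Known inconsistency: the published GCL_T ST abnormal count (19) does not
# match the bundled individual values against the published limit (18).
region_type,region,measure,f,n_normal,n_abnormal,pct_abnormal
ring,R1,mfPhNR_RAD,84.49,0,21,100
area,Area1,GCL_T,128.22,0,21,100
ring,R2,mfPhNR_RAD,42.79,0,21,100
area,Area2,GCL_T,113.34,0,21,100
ring,R3+R4,mfPhNR_RAD,57.61,0,21,100
area,Area3,GCL_T,53.23,1,20,95.2
sector,ST,mfPhNR_RAD,65.59,0,21,100
sector,ST,GCL_T,22.2,2,19,90.4
sector,IT,mfPhNR_RAD,66.99,0,21,100
sector,IT,GCL_T,67.3,0,21,100
sector,IN,mfPhNR_RAD,78.82,0,21,100
sector,IN,GCL_T,36.17,2,19,90.4
sector,SN,mfPhNR_RAD,103.99,0,21,100
sector,SN,GCL_T,22.03,6,15,71.4
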