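group,outcome,mean,sd,n
control,fev1_z,0.40,0.93,13
control,fvc_z,0.43,0.80,13
control,fev1_fvc_pct,87.26,5.67,13
control,tlc_z,0.62,0.87,13
control,rv_tlc_pct,27.81,6.58,13
control,lci2_5_TO,6.17,0.35,13
control,vdp_pct,15.53,4.55,13
control,qdp_pct,14.53,2.91,13
control,ddi_v,1.06,0.62,13
control,ddi_q,0.82,0.50,13
control,vqd_pct,2.05,1.89,13
small_CDH,fev1_z,-0.33,1.04,7
small_CDH,fvc_z,-0.51,1.29,7
small_CDH,fev1_fvc_pct,89.25,5.45,7
small_CDH,tlc_z,-0.61,1.21,6
small_CDH,rv_tlc_pct,28.38,4.36,6
small_CDH,lci2_5_TO,6.71,0.49,6
small_CDH,vdp_pct,15.03,1.49,7
small_CDH,qdp_pct,14.41,4.17,7
small_CDH,ddi_v,1.53,1.38,7
small_CDH,ddi_q,1.58,1.92,7
small_CDH,vqd_pct,2.31,2.39,7
large_CDH,fev1_z,-3.86,1.43,6
large_CDH,fvc_z,-3.54,2.30,6
large_CDH,fev1_fvc_pct,77.25,11.39,6
large_CDH,tlc_z,-0.96,0.87,6
large_CDH,rv_tlc_pct,45.82,5.36,6
large_CDH,lci2_5_TO,7.29,0.76,5
large_CDH,vdp_pct,24.12,3.46,6
large_CDH,qdp_pct,31.75,2.88,6
large_CDH,ddi_v,2.51,0.48,6
large_CDH,ddi_q,5.49,1.58,6
large_CDH,vqd_pct,12.02,3.24,6
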