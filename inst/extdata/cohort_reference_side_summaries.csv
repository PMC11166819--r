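group,outcome,side,mean,sd,n
control,vdp,nonaff,8.62,2.67,13
control,vdp,aff,6.91,2.52,13
small_CDH,vdp,nonaff,6.65,2.39,7
small_CDH,vdp,aff,8.38,2.42,7
large_CDH,vdp,nonaff,4.68,2.08,6
large_CDH,vdp,aff,19.44,2.45,6
control,qdp,nonaff,6.79,2.45,13
control,qdp,aff,7.74,1.18,13
small_CDH,qdp,nonaff,4.75,1.76,7
small_CDH,qdp,aff,9.66,5.03,7
large_CDH,qdp,nonaff,4.13,6.60,6
large_CDH,qdp,aff,27.61,8.60,6
control,ddi_v,nonaff,1.57,0.78,13
control,ddi_v,aff,2.60,2.12,13
small_CDH,ddi_v,nonaff,1.20,0.40,7
small_CDH,ddi_v,aff,3.92,3.63,7
large_CDH,ddi_v,nonaff,2.06,2.39,6
large_CDH,ddi_v,aff,5.07,1.71,6
control,ddi_q,nonaff,1.06,0.69,13
control,ddi_q,aff,2.14,1.40,13
small_CDH,ddi_q,nonaff,1.01,0.52,7
small_CDH,ddi_q,aff,3.53,3.91,7
large_CDH,ddi_q,nonaff,2.72,5.09,6
large_CDH,ddi_q,aff,9.59,5.13,6
control,vqd,nonaff,1.72,1.83,13
control,vqd,aff,2.45,2.44,13
small_CDH,vqd,nonaff,0.70,0.43,7
small_CDH,vqd,aff,4.22,5.34,7
large_CDH,vqd,nonaff,1.18,1.20,6
large_CDH,vqd,aff,22.11,7.71,6
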