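"compound_id","papp_caco2","papp_mdck","vdss","f_oral","cl_hepa_human","cl_hepa_rat","cl_micro","cl_int_u","fdamdd"
"sitagliptin",8e-06,1.99e-05,2.96,0.9,25,28,9,8,0.012
"LASSBio-2123",4.5e-06,1.15e-05,3.1,0.9,30,33,7.5,6.8,0.01
"LASSBio-2124",6e-06,1.55e-05,4.2,0.91,18,19,6.5,6.2,0.011
"LASSBio-2125",5e-06,1.3e-05,5.1,0.88,19,21,7,6.9,0.009
"LASSBio-2129",6.5e-06,1.77e-05,7.04,0.92,15,16,6,6.5,0.01
"LASSBio-2130",6.2e-06,1.6e-05,4,0.91,17,18,6.2,6.4,0.01
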