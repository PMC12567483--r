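"compound_id","mw","tpsa","hbd","logp","logd74","pka_basic"
"sitagliptin",407.31,77.04,1,1.5,0.75,7.7
"LASSBio-2123",395.38,85.94,2,2.53,1.95,6.6
"LASSBio-2124",353.31,67.48,2,2.75,2.45,6.55
"LASSBio-2125",404.21,67.48,2,3.82,2.94,6.7
"LASSBio-2129",371.3,67.48,2,2.8,2.32,6.46
"LASSBio-2130",353.31,67.48,2,2.85,2.28,6.5
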