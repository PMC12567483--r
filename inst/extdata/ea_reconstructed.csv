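"compound_id","target","ea"
"sitagliptin","2IKH",-9
"sitagliptin","4IXC",-8.8
"LASSBio-2123","2IKH",-8.8
"LASSBio-2123","4IXC",-8.4
"LASSBio-2124","2IKH",-8.3
"LASSBio-2124","4IXC",-8.6
"LASSBio-2125","2IKH",-8.9
"LASSBio-2125","4IXC",-8.2
"LASSBio-2129","2IKH",-11.085
"LASSBio-2129","4IXC",-10.352
"LASSBio-2130","2IKH",-8.1
"LASSBio-2130","4IXC",-8.5
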