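# Structures reconstructed from the published IUPAC name of LASSBio-2129 and
# the benzylidene-ring substituents of its analogs; sitagliptin is the control.
N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1ccc(OC)c(OC)c1	LASSBio-2123
N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1ccc(F)cc1	LASSBio-2124
N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1ccc(Cl)c(Cl)c1	LASSBio-2125
N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1ccc(F)c(F)c1	LASSBio-2129
N[C@@H](Cc1cc(F)c(F)cc1F)CC(=O)N/N=C/c1cccc(F)c1	LASSBio-2130
Fc1cc(c(F)cc1F)C[C@@H](N)CC(=O)N1CCn2c(nnc2C(F)(F)F)C1	sitagliptin
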