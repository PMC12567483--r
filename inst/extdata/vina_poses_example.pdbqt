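MODEL 1
REMARK VINA RESULT:     -8.598      0.000      0.000
ATOM      1  C   LIG A   1      14.200   0.100  23.500  1.00  0.00    +0.000 C 
ATOM      2  C   LIG A   1      15.600   0.100  23.500  1.00  0.00    +0.000 C 
ATOM      3  N   LIG A   1      16.300   1.200  23.900  1.00  0.00    +0.000 N 
ATOM      4  O   LIG A   1      13.500  -0.900  23.100  1.00  0.00    +0.000 O 
ENDMDL
MODEL 2
REMARK VINA RESULT:     -5.200      0.000      0.000
ATOM      1  C   LIG A   1      15.000   0.100  23.500  1.00  0.00    +0.000 C 
ATOM      2  C   LIG A   1      16.400   0.100  23.500  1.00  0.00    +0.000 C 
ATOM      3  N   LIG A   1      17.100   1.200  23.900  1.00  0.00    +0.000 N 
ATOM      4  O   LIG A   1      14.300  -0.900  23.100  1.00  0.00    +0.000 O 
ENDMDL
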