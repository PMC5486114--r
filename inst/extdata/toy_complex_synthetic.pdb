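REMARK synthetic toy complex fixture: one ALA+GLY protein fragment and
REMARK a GLC ligand; coordinates are artificial, for reader tests only
ATOM      1 N    ALA A   1      -1.300   0.900   0.100  1.00  0.00           N
ATOM      2 CA   ALA A   1      -0.600  -0.300   0.400  1.00  0.00           C
ATOM      3 HA   ALA A   1       0.000   0.000   0.000  1.00  0.00           H
ATOM      4 CB   ALA A   1       1.900   0.200   0.600  1.00  0.00           C
ATOM      5 HB1  ALA A   1       2.000   0.000  -0.500  1.00  0.00           H
ATOM      6 HB2  ALA A   1       2.600   1.550   0.400  1.00  0.00           H
ATOM      7 HB3  ALA A   1       2.600  -0.900   1.300  1.00  0.00           H
ATOM      8 C    ALA A   1      -0.900  -1.500  -0.400  1.00  0.00           C
ATOM      9 O    ALA A   1      -1.800  -1.500  -1.200  1.00  0.00           O
ATOM     10 CA   GLY A   2       4.600   3.200  -0.400  1.00  0.00           C
ATOM     11 HA2  GLY A   2       5.000   3.000   0.600  1.00  0.00           H
HETATM   12 C1   GLC B  10       3.600  -0.400   1.600  1.00  0.00           C
HETATM   13 H1   GLC B  10       4.000   0.000   1.900  1.00  0.00           H
HETATM   14 C2   GLC B  10       5.000   0.100   2.200  1.00  0.00           C
HETATM   15 H2   GLC B  10       5.500   0.500   2.500  1.00  0.00           H
HETATM   16 C3   GLC B  10       6.000   1.400   2.700  1.00  0.00           C
HETATM   17 H3   GLC B  10       6.500   1.800   3.000  1.00  0.00           H
END
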