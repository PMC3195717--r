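ATOM      1  CA  GLY A   1       2.300   0.000   0.000  1.00  0.00           C
ATOM      2  CA  GLY A   2      -0.399   2.265   1.500  1.00  0.00           C
ATOM      3  CA  GLY A   3      -2.161  -0.787   3.000  1.00  0.00           C
ATOM      4  CA  GLY A   4       1.150  -1.992   4.500  1.00  0.00           C
ATOM      5  CA  GLY A   5       1.762   1.478   6.000  1.00  0.00           C
ATOM      6  CA  GLY A   6      -1.762   1.478   7.500  1.00  0.00           C
ATOM      7  CA  GLY A   7      -1.150  -1.992   9.000  1.00  0.00           C
ATOM      8  CA  GLY A   8       2.161  -0.787  10.500  1.00  0.00           C
ATOM      9  CA  GLY A   9       0.399   2.265  12.000  1.00  0.00           C
ATOM     10  CA  GLY A  10      -2.300   0.000  13.500  1.00  0.00           C
ATOM     11  CA  GLY A  11       0.399  -2.265  15.000  1.00  0.00           C
ATOM     12  CA  GLY A  12       2.161   0.787  16.500  1.00  0.00           C
ATOM     13  CA  GLY A  13      -1.150   1.992  18.000  1.00  0.00           C
ATOM     14  CA  GLY A  14      -1.762  -1.478  19.500  1.00  0.00           C
ATOM     15  CA  GLY A  15       1.762  -1.478  21.000  1.00  0.00           C
ATOM     16  CA  GLY A  16       1.150   1.992  22.500  1.00  0.00           C
ATOM     17  CA  GLY A  17      -2.161   0.787  24.000  1.00  0.00           C
ATOM     18  CA  GLY A  18      -0.399  -2.265  25.500  1.00  0.00           C
ATOM     19  CA  GLY A  19       2.300  -0.000  27.000  1.00  0.00           C
ATOM     20  CA  GLY A  20      -0.399   2.265  28.500  1.00  0.00           C
ATOM     21  CA  GLY A  21      -2.161  -0.787  30.000  1.00  0.00           C
ATOM     22  CA  GLY A  22       1.150  -1.992  31.500  1.00  0.00           C
ATOM     23  CA  GLY A  23       1.762   1.478  33.000  1.00  0.00           C
ATOM     24  CA  GLY A  24      -1.762   1.478  34.500  1.00  0.00           C
ATOM     25  CA  GLY A  25      -1.150  -1.992  36.000  1.00  0.00           C
ATOM     26  CA  GLY A  26       2.161  -0.787  37.500  1.00  0.00           C
ATOM     27  CA  GLY A  27       0.399   2.265  39.000  1.00  0.00           C
ATOM     28  CA  GLY A  28      -2.300  -0.000  40.500  1.00  0.00           C
ATOM     29  CA  GLY A  29       0.399  -2.265  42.000  1.00  0.00           C
ATOM     30  CA  GLY A  30       2.161   0.787  43.500  1.00  0.00           C
END
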