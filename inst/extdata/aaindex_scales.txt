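H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7     4.2    -0.9    -1.3
//
H WERD780104
D Free energy change of epsilon(i) to alpha(Rh) (Wertz-Scheraga, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y
    -0.07   -0.4    -0.57   -0.8     0.17   -0.26   -0.63    0.27   -0.49    0.06
    -0.17   -0.45    0.03    0.4    -0.47   -0.11    0.09   -0.11   -0.61   -0.61
//
H OLSK800101
D Average internal preferences (Olsen, 1980)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y
     1.38    0       0.37    0.52    1.43    0.22    0.71    1.34    0.66    2.32
     1.47    0.15    1.78    1.72    0.85    0.86    0.89    1.99    0.82    0.47
//
H NAKH920108
D AA composition of MEM of multi-spanning proteins (Nakashima-Nishikawa, 1992)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y
     9.36    0.27    2.31    0.94    2.56    1.14    0.94    6.17    0.47   13.73
    16.64    0.58    3.93   10.99    1.96    5.58    4.68   12.43    2.2     3.13
//
H WOLR810101
D Hydration potential (Wolfenden et al., 1981)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y
     1.94  -19.92   -9.68  -10.95   -1.24   -9.38  -10.2     2.39  -10.27    2.15
     2.28   -9.52   -1.48   -0.76   -3.68   -5.06   -4.88    1.99   -5.88   -6.11
//
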