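H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
    3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.500   3.000   0.200   3.000  -1.000   0.200   3.000   0.000  -0.500  -1.800
   -1.800   3.000  -1.300  -2.500   0.000   0.300  -0.400  -3.400  -2.300  -1.500
//
H EISD840101
D Consensus normalized hydrophobicity scale (Eisenberg, 1984)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.620  -2.530  -0.780  -0.900   0.290  -0.850  -0.740   0.480  -0.400   1.380
    1.060  -1.500   0.640   1.190   0.120  -0.180  -0.050   0.810   0.260   1.080
//
H GRAR740102
D Polarity (Grantham, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    8.100  10.500  11.600  13.000   5.500  10.500  12.300   9.000  10.400   5.200
    4.900  11.300   5.700   5.200   8.000   9.200   8.600   5.400   6.200   5.900
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    6.000  10.760   5.410   2.770   5.050   5.650   3.220   5.970   7.590   6.020
    5.980   9.740   5.740   5.480   6.300   5.680   5.660   5.890   5.660   5.960
//
H ZIMJ680102
D Bulkiness (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   11.500  14.280  12.820  11.680  13.460  14.450  13.570   3.400  13.690  21.400
   21.400  15.710  16.250  19.800  17.430   9.470  15.770  21.670  18.030  21.570
//
H ZIMJ680103
D Polarity (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.000  52.000   3.380  49.700   1.480   3.530  49.900   0.000  51.600   0.130
    0.130  49.500   1.430   0.350   1.580   1.670   1.660   2.100   1.610   0.130
//
H BHAR880101
D Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.357   0.529   0.463   0.511   0.346   0.493   0.497   0.544   0.323   0.462
    0.365   0.466   0.295   0.314   0.509   0.507   0.444   0.305   0.420   0.386
//
H FAUJ830101
D Hydrophobic parameter pi (Fauchere-Pliska, 1983)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.310  -1.010  -0.600  -0.770   1.540  -0.220  -0.640   0.000   0.130   1.800
    1.700  -0.990   1.230   1.790   0.720  -0.040   0.260   2.250   0.960   1.220
//
H KLEP840101
D Net charge (Klein et al., 1984)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.000   1.000   0.000  -1.000   0.000   0.000  -1.000   0.000   0.000   0.000
    0.000   1.000   0.000   0.000   0.000   0.000   0.000   0.000   0.000   0.000
//
H CHOP780201
D Normalized frequency of alpha-helix (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.420   0.980   0.670   1.010   0.700   1.110   1.510   0.570   1.000   1.080
    1.210   1.160   1.450   1.130   0.570   0.770   0.830   1.080   0.690   1.060
//
H CHOP780202
D Normalized frequency of beta-sheet (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.830   0.930   0.890   0.540   1.190   1.100   0.370   0.750   0.870   1.600
    1.300   0.740   1.050   1.380   0.550   0.750   1.190   1.370   1.470   1.700
//
H CHOP780203
D Normalized frequency of beta-turn (Chou-Fasman, 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.660   0.950   1.560   1.460   1.190   0.980   0.740   1.560   0.950   0.470
    0.590   1.010   0.600   0.600   1.520   1.430   0.960   0.960   1.140   0.500
//
H ENGD860101
D Hydrophobicity index, GES scale (Engelman et al., 1986)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.600 -12.300  -4.800  -9.200   2.000  -4.100  -8.200   1.000  -3.000   3.100
    2.800  -8.800   3.400   3.700  -0.200   0.600   1.200   1.900  -0.700   2.600
//
H WIMW960101
D Free energy of transfer to POPC interface (Wimley-White, 1996)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.170   0.810   0.420   1.230  -0.240   0.580   2.020   0.010   0.960  -0.310
   -0.560   0.990  -0.230  -1.130   0.450   0.130   0.140  -1.850  -0.940   0.070
//
H CHOC760101
D Residue accessible surface area in tripeptide (Chothia, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  115.000 225.000 160.000 150.000 135.000 180.000 190.000  75.000 195.000 175.000
  170.000 200.000 185.000 210.000 145.000 115.000 140.000 255.000 230.000 155.000
//
H ZAMN720101
D Residue volume (Zamyatnin, 1972)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   88.600 173.400 114.100 111.100 108.500 143.800 138.400  60.100 153.200 166.700
  166.700 168.600 162.900 189.900 112.700  89.000 116.100 227.800 193.600 140.000
//
H MCMT640101
D Refractivity (McMeekin et al., 1964)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    4.340  26.660  13.280  12.000  35.770  17.560  17.260   0.000  21.810  19.060
   18.780  21.290  21.640  29.400  10.930   6.350  11.010  42.530  31.530  13.920
//
H JANJ780101
D Free energy of transfer from inside to outside of a globular protein (Janin, 1979)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.300  -1.400  -0.500  -0.600   0.900  -0.700  -0.700   0.300  -0.100   0.700
    0.500  -1.800   0.400   0.500  -0.300  -0.100  -0.200   0.300  -0.400   0.600
//
H FASG760101
D Molecular weight (Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   89.090 174.200 132.120 133.100 121.150 146.150 147.130  75.070 155.160 131.170
  131.170 146.190 149.210 165.190 115.130 105.090 119.120 204.240 181.190 117.150
//
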