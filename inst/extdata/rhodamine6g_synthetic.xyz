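# Synthetic idealized 3-D geometry of the rhodamine-6G cation
# (ETKDG-embedded, MMFF94-minimized; NOT experimental coordinates).
# Columns: label element x y z (Cartesian Angstrom)
label element x y z
C9 C -0.0206 0.5650 1.1041
P1 C 0.0745 1.6949 2.0713
P2 C 0.4003 3.0125 1.6948
C21 C 0.6824 3.4098 0.2990
O22 O 0.1667 4.3779 -0.2331
O31 O 1.6258 2.5952 -0.2347
C32 C 1.9738 2.8779 -1.5981
C33 C 1.0279 2.1523 -2.5369
P3 C 0.4026 4.0390 2.6513
P4 C 0.1063 3.7586 3.9849
P5 C -0.2111 2.4577 4.3680
P6 C -0.2352 1.4337 3.4187
CA1 C -1.2346 0.3352 0.2789
CA2 C -2.3496 1.1811 0.3232
CA3 C -3.4856 0.9504 -0.4811
CM1 C -4.6249 1.9357 -0.4045
CA4 C -3.5437 -0.1806 -1.3231
N15 N -4.6504 -0.3708 -2.1587
CE1 C -4.8753 -1.6497 -2.8218
CE2 C -6.1878 -1.6020 -3.5888
CA5 C -2.4086 -0.9981 -1.3830
CA6 C -1.2827 -0.7471 -0.5895
O13 O -0.2379 -1.6221 -0.7273
CB6 C 0.9283 -1.4056 -0.0100
CB5 C 1.9546 -2.2415 -0.2145
CB4 C 3.2455 -2.0803 0.5079
N16 N 4.2501 -2.8668 0.2916
CE3 C 4.4061 -3.9985 -0.6562
CE4 C 4.0724 -5.2926 0.0566
CB3 C 3.3394 -0.9646 1.5139
CM2 C 4.5985 -0.7508 2.3073
CB2 C 2.2791 -0.1540 1.6850
CB1 C 1.0221 -0.2957 0.9407
H32a H 2.9945 2.5116 -1.7496
H32b H 1.9869 3.9561 -1.7945
H33a H 1.0448 1.0751 -2.3424
H33b H 1.3082 2.3254 -3.5797
H33c H -0.0044 2.4863 -2.3912
HP3 H 0.6248 5.0633 2.3550
HP4 H 0.1062 4.5595 4.7216
HP5 H -0.4602 2.2443 5.4055
HP6 H -0.5161 0.4303 3.7346
HA2 H -2.3529 2.0519 0.9761
HM1a H -4.8755 2.3096 -1.4026
HM1b H -4.3673 2.8051 0.2099
HM1c H -5.5043 1.4612 0.0424
H15 H -5.5015 0.0169 -1.7585
HE1a H -4.9182 -2.4599 -2.0848
HE1b H -4.0683 -1.8610 -3.5319
HE2a H -6.1764 -0.8016 -4.3363
HE2b H -6.3628 -2.5512 -4.1044
HE2c H -7.0312 -1.4185 -2.9146
HA5 H -2.3754 -1.8495 -2.0550
HB5 H 1.8226 -3.0500 -0.9245
H16 H 5.0975 -2.7168 0.8459
HE3a H 5.4478 -3.9890 -0.9913
HE3b H 3.7666 -3.8369 -1.5276
HE4a H 3.0346 -5.3015 0.4076
HE4b H 4.2067 -6.1420 -0.6206
HE4c H 4.7203 -5.4485 0.9265
HM2a H 4.8292 -1.6372 2.9073
HM2b H 4.5138 0.0958 2.9973
HM2c H 5.4423 -0.5441 1.6408
HB2 H 2.3596 0.6593 2.4032
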