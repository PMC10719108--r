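# Four-Gaussian X-ray atomic form-factor coefficients,
#   f(s) = sum_i a_i exp(-b_i s^2) + c,  s = sin(theta)/lambda in 1/A,
# International Tables Vol. C style Cromer-Mann parameterization (the b_i are
# the conventional (sin(theta)/lambda)^2 coefficients).
# f(0) = sum(a_i) + c equals the species' electron count to table precision.
# Columns: species, nuclear charge z, electron count n, a1..a4, c, b1..b4.
species z n a1 a2 a3 a4 c b1 b2 b3 b4
H     1  1  0.489918  0.262003 0.196767   0.049879  0.001305 20.6593   7.74039 49.5519   2.20159
H1+   1  0  0.0       0.0      0.0        0.0       0.0       0.0      0.0      0.0      0.0
H1-   1  2  0.897661  0.565616 0.415815   0.116973  0.002389 53.1368  15.1870 186.576    3.56709
C     6  6  2.31000   1.02000  1.58860    0.865000  0.215600 20.8439  10.2075   0.568700 51.6512
N     7  7 12.2126    3.13220  2.01250    1.16630 -11.529     0.005700 9.89330 28.9975    0.582600
O     8  8  3.04850   2.28680  1.54630    0.867000  0.250800 13.2771   5.70110  0.323900 32.9089
O1-   8  9  4.19160   1.63969  1.52673  -20.307    21.9412   12.8573   4.17236 47.0179   -0.01404
Cl   17 17 11.4604    7.19640  6.25560    1.64550  -9.5574    0.010400 1.16620 18.5194   47.7784
Cl1- 17 18 18.2915    7.20840  6.53370    2.33860 -16.378     0.006600 1.17170 19.5424   60.4486
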