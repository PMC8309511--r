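t,x,y,valid_l,valid_r
0,-10.0446,-4.952,TRUE,TRUE
25,-9.2552,-5.0088,TRUE,TRUE
50,-8.5596,-5.0402,TRUE,TRUE
75,-7.9099,-4.9687,TRUE,TRUE
100,-7.1772,-4.921,TRUE,TRUE
125,-6.4054,-4.9708,TRUE,TRUE
150,-5.7194,-4.9971,TRUE,TRUE
175,-5.0643,-4.9297,TRUE,TRUE
200,-4.3242,-4.8816,TRUE,TRUE
225,-3.5495,-4.9314,TRUE,TRUE
250,-2.8698,-4.9598,TRUE,TRUE
275,-2.2147,-4.8933,TRUE,TRUE
300,-1.4688,-4.8484,TRUE,TRUE
325,-0.6797,-4.9105,TRUE,TRUE
350,0.0123,-4.9408,TRUE,TRUE
375,0.6546,-4.8718,TRUE,TRUE
400,1.3918,-4.8251,TRUE,TRUE
425,2.1772,-4.8797,TRUE,TRUE
450,2.8731,-4.9168,TRUE,TRUE
475,3.5291,-4.854,TRUE,TRUE
500,4.2767,-4.8129,TRUE,TRUE
525,5.0641,-4.8727,TRUE,TRUE
550,5.7596,-4.9141,TRUE,TRUE
575,6.4152,-4.8627,TRUE,TRUE
600,7.1639,-4.8302,TRUE,TRUE
625,7.9509,-4.8947,TRUE,TRUE
650,8.6431,-4.9423,TRUE,TRUE
675,10.8142,-5.2458,TRUE,TRUE
700,10.2076,-4.9019,TRUE,TRUE
725,9.6413,-4.6534,TRUE,TRUE
750,8.9855,-4.3736,TRUE,TRUE
775,8.2908,-3.999,TRUE,TRUE
800,7.6884,-3.645,TRUE,TRUE
825,7.1233,-3.393,TRUE,TRUE
850,6.4654,-3.1079,TRUE,TRUE
875,5.7685,-2.7249,TRUE,TRUE
900,5.1597,-2.3602,TRUE,TRUE
925,4.3152,-2.2157,TRUE,TRUE
950,3.6573,-1.9223,TRUE,TRUE
975,2.962,-1.5324,TRUE,TRUE
1000,2.3554,-1.1641,TRUE,TRUE
1025,1.7771,-0.8962,TRUE,TRUE
1050,1.1026,-0.6126,TRUE,TRUE
1075,0.3913,-0.2406,TRUE,TRUE
1100,-0.2237,0.105,TRUE,TRUE
1125,-0.7983,0.3526,TRUE,TRUE
1150,-1.4656,0.6231,TRUE,TRUE
1175,-2.166,0.9902,TRUE,TRUE
1200,-2.7775,1.3354,TRUE,TRUE
1225,-3.353,1.5846,TRUE,TRUE
1250,-4.0181,1.8554,TRUE,TRUE
1275,-4.7298,2.2314,TRUE,TRUE
1300,-5.3431,2.5783,TRUE,TRUE
1325,-7.733,3.7368,TRUE,TRUE
1350,-8.4042,4.013,TRUE,TRUE
1375,-9.1159,4.3917,TRUE,TRUE
1400,-9.7352,4.7491,TRUE,TRUE
1425,-9.8611,4.9086,TRUE,TRUE
1450,-9.1841,4.8739,TRUE,TRUE
1475,-8.5439,4.9302,TRUE,TRUE
1500,-7.809,4.9609,TRUE,TRUE
1525,-7.0313,4.8917,TRUE,TRUE
1550,-6.3502,4.848,TRUE,TRUE
1575,-5.7108,4.908,TRUE,TRUE
1600,-4.9788,4.9449,TRUE,TRUE
1625,-4.2066,4.881,TRUE,TRUE
1650,-3.5219,4.8354,TRUE,TRUE
1675,-2.8765,4.8879,TRUE,TRUE
1700,-2.1418,4.9207,TRUE,TRUE
1725,-1.3668,4.8545,TRUE,TRUE
1750,-0.6846,4.8115,TRUE,TRUE
1775,-0.0423,4.8679,TRUE,TRUE
1800,0.6923,4.9019,TRUE,TRUE
1825,1.4746,4.8334,TRUE,TRUE
1850,2.1615,4.7882,TRUE,TRUE
1875,2.8062,4.8426,FALSE,FALSE
1900,3.541,4.877,TRUE,TRUE
1925,4.3184,4.8105,TRUE,TRUE
1950,5.0043,4.7664,TRUE,TRUE
1975,5.6525,4.8195,TRUE,TRUE
2000,6.3937,4.85,TRUE,TRUE
2025,7.1681,4.7865,TRUE,TRUE
2050,7.8487,4.7477,TRUE,TRUE
2075,8.4911,4.806,TRUE,TRUE
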