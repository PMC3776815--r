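sex,agemos,L,M,S
male,156,-2.5,18.94,0.125
male,162,-2.47,19.2445,0.1254
male,168,-2.44,19.538,0.1258
male,174,-2.41,19.8205,0.1262
male,180,-2.38,20.092,0.1266
male,186,-2.35,20.3525,0.127
male,192,-2.32,20.602,0.1274
male,198,-2.29,20.8405,0.1278
male,204,-2.26,21.068,0.1282
male,210,-2.23,21.2845,0.1286
male,216,-2.2,21.49,0.129
male,222,-2.17,21.6845,0.1294
male,228,-2.14,21.868,0.1298
male,234,-2.11,22.0405,0.1302
male,240,-2.08,22.202,0.1306
female,156,-2.2,19.36,0.138
female,162,-2.19,19.6272,0.1384
female,168,-2.18,19.879,0.1388
female,174,-2.17,20.1152,0.1392
female,180,-2.16,20.336,0.1396
female,186,-2.15,20.5412,0.14
female,192,-2.14,20.731,0.1404
female,198,-2.13,20.9052,0.1408
female,204,-2.12,21.064,0.1412
female,210,-2.11,21.2073,0.1416
female,216,-2.1,21.335,0.142
female,222,-2.09,21.4472,0.1424
female,228,-2.08,21.544,0.1428
female,234,-2.07,21.6252,0.1432
female,240,-2.06,21.691,0.1436
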