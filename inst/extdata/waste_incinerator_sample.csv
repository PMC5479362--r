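"B","F","W","C","E","MW","D","L","ME"
1,NA,1,NA,-10.7444,0.4174,-0.0082,38.1874,4.4888
2,1,1,-0.6366,-0.848,0.0182,33.9681,2.9188,-0.2942
NA,NA,1,-3e-04,-0.0011,2.6485,32.2174,0.051,9.4387
2,1,1,-0.092,-3.239,NA,9.7888,7.212,5.0439
2,1,2,-2.0554,NA,1.9721,131.8076,-0.2507,68.2391
2,2,2,-0.5222,-2e-04,5.3563,24.164,9e-04,40.2234
1,1,NA,-18.0146,4e-04,2.8046,33.8903,0.1451,30.4034
1,1,1,-3.5048,-3.9216,0.0028,2.0891,NA,1.8134
2,1,2,-0.1019,-0.0211,2.2985,31.163,0.2516,18.9473
1,1,2,-0.5889,0,6.5648,22.2661,0.0627,9.9122
2,1,1,-0.4618,-3.1385,1.0914,0.4509,14.1966,0.0071
1,2,1,-11.5434,-9.8383,0.7064,0.0659,26.276,0.6667
1,1,NA,NA,0,23.0278,8.9996,11.9141,22.1673
2,2,2,-2.0737,-0.7296,10.5647,31.7083,4.6618,17.1765
1,1,1,-14.7497,-0.4692,0.301,0.3841,16.9556,1.6949
NA,1,2,-0.7499,0.1593,1.3664,69.6173,NA,31.5006
1,NA,1,-15.4551,-5e-04,11.0447,2.3457,NA,40.1114
1,1,1,-6.9447,-1.1172,0.7309,NA,0.175,NA
1,1,1,-5.8864,NA,9e-04,-0.0038,20.6604,NA
1,NA,1,-8.3474,-0.0073,0.2273,7.0332,NA,NA
1,2,1,-9.3582,-1.2131,0.0292,5.2405,0,5e-04
1,1,1,-13.0694,-0.9306,0.0384,1.9573,16.7785,0.3485
1,1,2,-17.7356,0,0.8512,2.5551,2.9607,0.6512
1,1,2,-3.6156,NA,3.8634,3.0043,5.9774,0.0119
1,1,2,-7.8539,0.9211,4.8167,100.3295,-3.2552,43.5395
2,2,1,-0.1617,-14.8645,-0.0026,6.5061,9.4921,0.1381
1,1,1,-19.2817,-4.2163,-2.8197,-0.0231,101.4766,-0.0192
2,1,1,-0.7472,0.2969,0.0426,30.9925,0.0018,3.4032
2,1,1,-0.2516,-0.6614,0.1386,11.6339,2.3351,8.4936
1,2,NA,-8.174,NA,0.6175,0.0686,75.3102,0.8087
1,1,2,-9.325,-2.1793,3.6167,1.0708,27.1946,0.3132
1,NA,2,-14.3182,-0.6243,5.3096,1.5478,49.5171,NA
1,1,2,NA,0.3964,0.6153,30.7897,0.5158,11.1951
1,1,1,-4.0116,-0.4625,0.7806,8.2187,NA,6.6774
1,1,2,-1.0025,NA,NA,34.2153,0.0368,48.3464
2,1,1,-0.8741,6e-04,0.2732,14.154,14.1365,6.5698
1,1,1,-12.909,-0.0465,NA,NA,1.2605,23.5352
1,1,1,-22.6379,-2.0905,0.4041,7.8897,6.2754,4.9297
2,1,2,-2.4517,0.2009,4.5446,47.088,0.0831,NA
2,2,1,-0.6723,-9.3763,0.2856,2.9974,52.1034,6.115
1,1,2,-3.0158,-8e-04,5.4378,44.9441,1e-04,11.2269
2,1,1,-0.6395,NA,1.4321,0.5236,NA,-0.0164
NA,NA,2,-18.4396,-0.0126,5.522,9.1627,NA,5.4591
2,1,2,-0.2545,0.102,6.7765,54.5341,0.0312,22.75
1,1,2,-24.4849,2.671,NA,42.8984,-0.001,NA
1,1,1,-10.6536,-0.3823,0.0221,10.8665,3.7384,18.8079
2,1,2,-1.6146,0.1572,13.376,54.0094,0.0028,125.5687
1,1,2,-28.8525,-0.0356,0.4672,39.2992,8e-04,26.3439
1,1,NA,NA,NA,NA,0.4802,22.9015,-0.001
2,NA,2,-2.4124,-0.8261,5.2644,9.2339,2.0704,13.6438
1,2,1,-10.4025,-5.2158,1.2503,0.1578,1.7295,2.9159
1,1,1,-1.8875,-0.2364,0.0253,3.1158,-4e-04,0.7356
2,2,1,-0.2762,-6.8416,0.2094,0.3967,8.4393,NA
1,1,2,-8.7341,0.199,0.0953,8.0868,20.1539,0.3313
1,1,2,-5.076,0.0509,NA,25.8006,3.9502,6.009
1,2,1,-5.6522,-3.9704,0.0012,3e-04,59.0208,1.7362
1,2,2,-1.2922,0.0092,2.5089,44.8814,2.0649,30.1629
2,1,1,NA,NA,-0.0083,NA,8.0277,0.1389
1,1,NA,-5.1125,0.0103,5.1574,NA,-0.3175,40.6125
NA,2,2,-0.5307,-2.8057,6.798,4.6716,7.8693,56.7589
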