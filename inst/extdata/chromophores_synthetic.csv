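wavelength_nm,eps_hbo2,eps_hb,mu_melanin,mu_water,mu_fat,mus_reduced
450,14.28,15.25,30.820995,0.002,0.001,5.331118
455,11.9905,12.947226,29.750223,0.002,0.001,5.249282
460,10.075416,10.99797,28.727751,0.002,0.001,5.169575
465,8.473516,9.34796,27.750911,0.002,0.001,5.091922
470,7.133584,7.951257,26.817207,0.002,0.001,5.016246
475,6.012778,6.768973,25.924306,0.002,0.001,4.942478
480,5.075265,5.768195,25.070023,0.002,0.001,4.870551
485,4.291068,4.921071,24.252311,0.002,0.001,4.8004
490,3.635118,4.204102,23.469251,0.002,0.001,4.731963
495,3.086469,3.597769,22.719044,0.002,0.001,4.665182
500,2.627953,3.087151,22,0.002,0.001,4.6
505,2.248441,2.665393,21.310532,0.002,0.001,4.536364
510,1.959854,2.344135,20.649148,0.002,0.001,4.474223
515,1.868034,2.176442,20.014445,0.002,0.001,4.413526
520,2.341926,2.292507,19.405105,0.002,0.001,4.354228
525,4.134948,2.927745,18.819883,0.002,0.001,4.296282
530,7.908561,4.390692,18.257609,0.002,0.001,4.239646
535,12.925515,6.910883,17.71718,0.002,0.001,4.184278
540,16.468531,10.380112,17.197553,0.002,0.001,4.130138
545,15.923993,14.148001,16.697747,0.002,0.001,4.077188
550,11.665965,17.11421,16.216835,0.002,0.001,4.025391
555,6.770106,18.202961,15.753939,0.002,0.001,3.974712
560,4.28446,18.012203,15.308231,0.002,0.001,3.925117
565,5.772755,14.870091,14.878929,0.002,0.001,3.876573
570,10.632539,10.918115,14.46529,0.002,0.001,3.82905
575,14.979008,7.252029,14.066615,0.002,0.001,3.782517
580,14.342899,4.51726,13.682237,0.002,0.001,3.736944
585,9.231854,2.816555,13.311528,0.002,0.001,3.692305
590,4.085847,1.914271,12.953892,0.002,0.001,3.648573
595,1.390107,1.494934,12.608761,0.002,0.001,3.605721
600,0.535877,1.315175,12.275599,0.002,0.001,3.563724
605,0.358817,1.235608,11.953897,0.002,0.001,3.522559
610,0.328765,1.192478,11.64317,0.002,0.001,3.482203
615,0.319641,1.161665,11.342958,0.002,0.001,3.442633
620,0.313451,1.1354,11.052825,0.002,0.001,3.403827
625,0.308435,1.111439,10.772355,0.002001,0.001,3.365765
630,0.304344,1.089105,10.501152,0.002001,0.001,3.328427
635,0.301046,1.068121,10.23884,0.002002,0.001,3.291794
640,0.298434,1.048306,9.985062,0.002004,0.001,3.255846
645,0.296426,1.029521,9.739476,0.002006,0.001,3.220566
650,0.294955,1.011649,9.501758,0.00201,0.001,3.185937
655,0.293972,0.994597,9.271597,0.002016,0.001,3.151941
660,0.29344,0.9783,9.048698,0.002026,0.001,3.118562
665,0.293337,0.962737,8.83278,0.002042,0.001,3.085784
670,0.293649,0.947958,8.623575,0.002065,0.001,3.053593
675,0.294375,0.93415,8.420825,0.002101,0.001,3.021973
680,0.29552,0.921739,8.224285,0.002154,0.001,2.99091
685,0.2971,0.911554,8.033723,0.002233,0.001,2.960391
690,0.299136,0.90506,7.848915,0.002346,0.001,2.930401
695,0.301658,0.904633,7.669646,0.002506,0.001,2.900929
700,0.304702,0.913813,7.495713,0.002732,0.001,2.871961
705,0.308308,0.937425,7.326921,0.003043,0.001,2.843486
710,0.312525,0.98137,7.163083,0.003465,0.001,2.815491
715,0.317404,1.051939,7.00402,0.004031,0.001,2.787965
720,0.323002,1.154511,6.849561,0.004776,0.001,2.760898
725,0.329378,1.291746,6.699541,0.005742,0.001,2.734278
730,0.336594,1.461583,6.553805,0.006974,0.001,2.708095
735,0.344717,1.655659,6.412202,0.008521,0.001,2.682338
740,0.35381,1.858845,6.274588,0.010432,0.001,2.656999
745,0.36394,2.050462,6.140824,0.012752,0.001,2.632068
750,0.37517,2.207279,6.010777,0.015521,0.001,2.607535
755,0.387563,2.307821,5.884322,0.018769,0.001,2.583391
760,0.401177,2.336878,5.761336,0.02251,0.001,2.559628
765,0.416062,2.288949,5.641701,0.02674,0.001,2.536237
770,0.432264,2.169524,5.525306,0.03143,0.001,2.51321
775,0.449821,1.9938,5.412043,0.036527,0.001,2.49054
780,0.468757,1.783243,5.301808,0.041948,0.001,2.468217
785,0.489087,1.561067,5.194501,0.047583,0.001,2.446236
790,0.510813,1.347943,5.090026,0.053294,0.001,2.424588
795,0.533919,1.158984,4.988292,0.058926,0.001,2.403266
800,0.558376,1.002539,4.889211,0.064304,0.001,2.382264
805,0.584134,0.880653,4.792696,0.069251,0.001,2.361574
810,0.611128,0.790651,4.698667,0.073589,0.001,2.341191
815,0.639271,0.727133,4.607044,0.077157,0.001,2.321107
820,0.668457,0.683789,4.517752,0.079817,0.001,2.301317
825,0.69856,0.654693,4.430717,0.081463,0.001,2.281814
830,0.729434,0.634997,4.345871,0.082034,0.001,2.262593
835,0.760915,0.621132,4.263144,0.081514,0.001001,2.243648
840,0.792817,0.610688,4.182471,0.079939,0.001005,2.224973
845,0.824941,0.602163,4.103791,0.077398,0.001014,2.206564
850,0.857071,0.594685,4.027042,0.074036,0.00104,2.188413
855,0.888978,0.587779,3.952166,0.070052,0.001107,2.170517
860,0.920421,0.581201,3.879106,0.065701,0.00127,2.152871
865,0.951155,0.574834,3.807809,0.061302,0.001639,2.135469
870,0.980925,0.568623,3.738222,0.057236,0.002419,2.118307
875,1.009479,0.562545,3.670295,0.053962,0.003954,2.10138
880,1.036564,0.556588,3.603978,0.052022,0.006771,2.084683
885,1.061936,0.550746,3.539225,0.052046,0.011578,2.068213
890,1.085357,0.545017,3.475991,0.054753,0.019189,2.051964
895,1.106605,0.539397,3.414232,0.060937,0.030346,2.035933
900,1.125473,0.533884,3.353904,0.071429,0.04542,2.020116
905,1.141774,0.528476,3.294968,0.087041,0.064083,2.004508
910,1.155345,0.523171,3.237384,0.108478,0.085052,1.989106
915,1.166048,0.517968,3.181114,0.136233,0.106073,1.973905
920,1.173772,0.512863,3.12612,0.17046,0.124235,1.958903
925,1.178439,0.507856,3.072367,0.210855,0.136606,1.944095
930,1.180001,0.502945,3.019821,0.256558,0.141,1.929477
935,1.178439,0.498127,2.968449,0.306101,0.136606,1.915048
940,1.173772,0.4934,2.918217,0.357425,0.124235,1.900802
945,1.166047,0.488764,2.869095,0.407975,0.106073,1.886737
950,1.155344,0.484216,2.821052,0.45488,0.085052,1.872849
955,1.141773,0.479755,2.77406,0.495204,0.064083,1.859136
960,1.125472,0.475379,2.72809,0.526231,0.04542,1.845594
965,1.106604,0.471086,2.683115,0.545758,0.030346,1.83222
970,1.085356,0.466875,2.639108,0.552346,0.019189,1.819011
975,1.061934,0.462744,2.596043,0.545484,0.011578,1.805965
980,1.036561,0.458692,2.553896,0.525654,0.006771,1.793079
985,1.009475,0.454717,2.512643,0.494263,0.003954,1.780349
990,0.980921,0.450817,2.47226,0.45348,0.002419,1.767773
995,0.95115,0.446992,2.432724,0.405986,0.001639,1.755349
1000,0.920415,0.44324,2.394014,0.354675,0.00127,1.743074
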