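# Site-specific collagen PTM catalog of zebrafish heart ECM (published
# summary table), transcribed verbatim: one row per printed site entry.
# Categories: HYP3 = 3-hydroxyproline, HYK = hydroxylysine,
# GHYK = galactosyl-hydroxylysine, GGHYK = glucosylgalactosyl-hydroxylysine.
# Positions are full-length chain coordinates. The COL5A2a GGHYK entry 761
# is printed twice in the source table; both entries are kept (the printed
# grand totals count it twice) and the duplicate is flagged.
chain_id	category	position	note
COL1A1a	HYP3	176
COL1A1a	HYP3	188
COL1A1a	HYP3	317
COL1A1a	HYP3	401
COL1A1a	HYP3	443
COL1A1a	HYP3	446
COL1A1a	HYP3	551
COL1A1a	HYP3	623
COL1A1a	HYP3	707
COL1A1a	HYP3	755
COL1A1a	HYP3	800
COL1A1a	HYP3	854
COL1A1a	HYP3	869
COL1A1a	HYP3	878
COL1A1a	HYP3	881
COL1A1a	HYP3	911
COL1A1a	HYP3	980
COL1A1a	HYP3	992
COL1A1a	HYP3	1034
COL1A1a	HYP3	1103
COL1A1a	HYP3	1106
COL1A1a	HYP3	1148
COL1A1a	HYP3	1166
COL1A1a	HYP3	1169
COL1A1a	HYK	261
COL1A1a	HYK	270
COL1A1a	HYK	336
COL1A1a	HYK	381
COL1A1a	HYK	414
COL1A1a	HYK	426
COL1A1a	HYK	432
COL1A1a	HYK	504
COL1A1a	HYK	522
COL1A1a	HYK	570
COL1A1a	HYK	596
COL1A1a	HYK	641
COL1A1a	HYK	693
COL1A1a	HYK	726
COL1A1a	HYK	735
COL1A1a	HYK	765
COL1A1a	HYK	810
COL1A1a	HYK	819
COL1A1a	HYK	846
COL1A1a	HYK	918
COL1A1a	HYK	1017
COL1A1a	HYK	1080
COL1A1a	HYK	1191
COL1A1a	GHYK	261
COL1A1a	GHYK	270
COL1A1a	GHYK	432
COL1A1a	GHYK	504
COL1A1a	GHYK	570
COL1A1a	GHYK	693
COL1A1a	GHYK	819
COL1A1a	GHYK	846
COL1A1a	GHYK	1191
COL1A1a	GGHYK	261
COL1A1a	GGHYK	270
COL1A1a	GGHYK	432
COL1A1a	GGHYK	504
COL1A1a	GGHYK	522
COL1A1a	GGHYK	570
COL1A1a	GGHYK	693
COL1A1a	GGHYK	726
COL1A1a	GGHYK	819
COL1A1a	GGHYK	846
COL1A1a	GGHYK	1017
COL1A1b	HYP3	176
COL1A1b	HYP3	191
COL1A1b	HYP3	302
COL1A1b	HYP3	320
COL1A1b	HYP3	404
COL1A1b	HYP3	470
COL1A1b	HYP3	554
COL1A1b	HYP3	758
COL1A1b	HYP3	872
COL1A1b	HYP3	881
COL1A1b	HYP3	914
COL1A1b	HYP3	938
COL1A1b	HYP3	983
COL1A1b	HYP3	1031
COL1A1b	HYP3	1109
COL1A1b	HYP3	1151
COL1A1b	HYP3	1175
COL1A1b	HYK	215
COL1A1b	HYK	264
COL1A1b	HYK	273
COL1A1b	HYK	339
COL1A1b	HYK	384
COL1A1b	HYK	417
COL1A1b	HYK	429
COL1A1b	HYK	525
COL1A1b	HYK	573
COL1A1b	HYK	618
COL1A1b	HYK	696
COL1A1b	HYK	738
COL1A1b	HYK	746
COL1A1b	HYK	768
COL1A1b	HYK	813
COL1A1b	HYK	849
COL1A1b	HYK	900
COL1A1b	HYK	1020
COL1A1b	HYK	1193
COL1A1b	GHYK	264
COL1A1b	GHYK	273
COL1A1b	GHYK	849
COL1A1b	GHYK	1020
COL1A1b	GGHYK	264
COL1A1b	GGHYK	273
COL1A1b	GGHYK	339
COL1A1b	GGHYK	849
COL1A2	HYP3	56
COL1A2	HYP3	59
COL1A2	HYP3	244
COL1A2	HYP3	286
COL1A2	HYP3	361
COL1A2	HYP3	451
COL1A2	HYP3	469
COL1A2	HYP3	673
COL1A2	HYP3	718
COL1A2	HYP3	787
COL1A2	HYP3	820
COL1A2	HYP3	838
COL1A2	HYP3	925
COL1A2	HYP3	1066
COL1A2	HYP3	1081
COL1A2	HYK	74
COL1A2	HYK	179
COL1A2	HYK	188
COL1A2	HYK	254
COL1A2	HYK	299
COL1A2	HYK	344
COL1A2	HYK	350
COL1A2	HYK	454
COL1A2	HYK	488
COL1A2	HYK	500
COL1A2	HYK	533
COL1A2	HYK	578
COL1A2	HYK	644
COL1A2	HYK	647
COL1A2	HYK	683
COL1A2	HYK	731
COL1A2	HYK	737
COL1A2	HYK	836
COL1A2	HYK	935
COL1A2	HYK	998
COL1A2	HYK	1004
COL1A2	GHYK	74
COL1A2	GHYK	188
COL1A2	GHYK	254
COL1A2	GHYK	344
COL1A2	GHYK	350
COL1A2	GHYK	644
COL1A2	GGHYK	74
COL1A2	GGHYK	167
COL1A2	GGHYK	188
COL1A2	GGHYK	254
COL1A2	GGHYK	299
COL1A2	GGHYK	578
COL1A2	GGHYK	644
COL1A2	GGHYK	647
COL1A2	GGHYK	935
COL4A1	HYP3	201
COL4A1	HYP3	204
COL4A1	HYP3	294
COL4A1	HYP3	297
COL4A1	HYP3	1338	printed lowercase p
COL4A1	GGHYK	463
COL4A1	GGHYK	466
COL4A1	GGHYK	882
COL4A1	GGHYK	909
COL4A1	GGHYK	1149
COL4A1	GGHYK	1179
COL4A1	GGHYK	1182
COL5A1	HYP3	686
COL5A1	HYP3	746
COL5A1	HYP3	824
COL5A1	HYP3	1112
COL5A1	HYP3	1115
COL5A1	HYP3	1163
COL5A1	HYP3	1166
COL5A1	HYP3	1190
COL5A1	HYP3	1193
COL5A1	HYP3	1253
COL5A1	HYP3	1421
COL5A1	HYP3	1424
COL5A1	HYK	1134
COL5A1	HYK	1296
COL5A1	HYK	1329
COL5A1	HYK	1497
COL5A1	HYK	1578
COL5A1	HYK	1581
COL5A1	HYK	1592
COL5A1	HYK	1604
COL5A1	HYK	1644
COL5A1	GHYK	1344
COL5A1	GGHYK	623
COL5A1	GGHYK	626
COL5A1	GGHYK	753
COL5A1	GGHYK	813
COL5A1	GGHYK	945
COL5A1	GGHYK	1104
COL5A1	GGHYK	1209
COL5A1	GGHYK	1245
COL5A1	GGHYK	1290
COL5A1	GGHYK	1338
COL5A1	GGHYK	1383
COL5A1	GGHYK	1455
COL5A1	GGHYK	1482
COL5A1	GGHYK	1578
COL5A1	GGHYK	1581
COL5A2a	HYP3	241
COL5A2a	HYP3	277
COL5A2a	HYP3	532
COL5A2a	HYP3	661
COL5A2a	HYP3	868
COL5A2a	HYP3	901
COL5A2a	HYP3	937
COL5A2a	HYP3	967
COL5A2a	HYP3	1105
COL5A2a	HYK	280
COL5A2a	HYK	329
COL5A2a	HYK	449
COL5A2a	HYK	482
COL5A2a	HYK	494
COL5A2a	HYK	709
COL5A2a	HYK	749
COL5A2a	HYK	803
COL5A2a	HYK	878
COL5A2a	HYK	986
COL5A2a	HYK	1036
COL5A2a	HYK	1078
COL5A2a	HYK	1124
COL5A2a	HYK	1135
COL5A2a	GGHYK	329
COL5A2a	GGHYK	338
COL5A2a	GGHYK	500
COL5A2a	GGHYK	557
COL5A2a	GGHYK	572
COL5A2a	GGHYK	761
COL5A2a	GGHYK	761	printed duplicate
COL5A2a	GGHYK	794
COL5A2a	GGHYK	638
COL5A2a	GGHYK	803
COL5A2a	GGHYK	887
COL6A1	HYP3	574
COL6A1	HYP3	577
COL6A1	HYK	482
COL6A1	HYK	538
COL6A1	GGHYK	398
COL6A1	GGHYK	488
COL6A1	GGHYK	538
COL6A1	GGHYK	560
COL6A1	GGHYK	563
COL6A3	HYK	1796
COL6A3	HYK	1975
COL6A3	GGHYK	1660
COL6A3	GGHYK	1778
COL6A3	GGHYK	1796
COL6A3	GGHYK	1711
COL6A3	GGHYK	1963
COL6A3	GGHYK	1880
COL6A3	GGHYK	1889
COL6A2	HYP3	470
COL6A2	HYK	387
COL6A2	GHYK	539
COL6A2	GGHYK	339
COL6A2	GGHYK	387
COL6A2	GGHYK	426
COL6A2	GGHYK	435
COL6A2	GGHYK	438
COL6A2	GGHYK	456
COL6A2	GGHYK	459
COL6A2	GGHYK	539
COL6A2	GGHYK	545
COL11A1a	HYP3	919
COL11A1a	HYK	1313
COL11A1a	GHYK	1217
COL11A1a	GHYK	1304
COL11A1a	GGHYK	911
COL11A1a	GGHYK	1148
COL11A1a	GGHYK	1151
COL4A2	HYP3	339
COL4A2	HYP3	555
COL4A2	HYP3	613
COL4A2	HYK	593
COL4A2	HYK	704
COL4A2	HYK	707
COL4A2	HYK	1620
COL4A2	HYK	1651
COL4A2	GHYK	689
COL4A2	GGHYK	54
COL4A2	GGHYK	72
COL4A2	GGHYK	318
COL4A2	GGHYK	567
COL4A2	GGHYK	582
COL4A2	GGHYK	593
COL4A2	GGHYK	662
COL4A2	GGHYK	674
COL4A2	GGHYK	689
COL4A2	GGHYK	704
COL4A2	GGHYK	707
COL4A2	GGHYK	725
COL4A2	GGHYK	948
COL4A2	GGHYK	951
COL4A2	GGHYK	969
COL4A2	GGHYK	1045
COL4A2	GGHYK	1048
COL4A2	GGHYK	1076
COL4A2	GGHYK	1235
COL4A2	GGHYK	1247
COL4A2	GGHYK	1283
COL4A2	GGHYK	1292
COL4A2	GGHYK	1331
COL4A2	GGHYK	1346
COL4A5	HYP3	93
COL4A5	HYK	127
COL4A5	HYK	214
COL4A5	GHYK	225
COL4A5	GGHYK	225
COL6A4a	GHYK	1501
COL6A4a	GGHYK	1490
COL6A4a	GGHYK	1787
COL6A4a	GGHYK	1796
COL6A4a	GGHYK	2148
COL2A1a	HYK	612
COL2A1a	GHYK	423
COL2A1a	GGHYK	423
COL2A1a	GGHYK	1178
COL16A1	HYK	1008
COL16A1	HYK	1343
COL16A1	HYK	1495
COL16A1	HYK	1498
COL16A1	GGHYK	644
COL16A1	GGHYK	654
COL16A1	GGHYK	1008
COL16A1	GGHYK	1233
COL11A1b	GGHYK	1191
COL11A1b	GGHYK	1400
COL5A2b	HYP3	838
COL5A2b	GGHYK	731
COL11A2	HYP3	1133
COL11A2	HYK	959
COL11A2	HYK	963
COL11A2	GGHYK	1188
COL11A2	GGHYK	1197
COL11A2	GGHYK	1200
COL11A2	GGHYK	1203
COL7A1	GGHYK	1504
COL7A1	GGHYK	2136
COL5A3b	HYP3	437
COL5A3b	HYP3	467
COL22A1	HYK	495
COL22A1	HYK	1128
COL22A1	GHYK	788
COL22A1	GHYK	1538
COL22A1	GGHYK	498
COL22A1	GGHYK	513
COL22A1	GGHYK	785
COL17A1a	HYP3	1156
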