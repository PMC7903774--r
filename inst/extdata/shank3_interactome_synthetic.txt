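shank3
homer1
dlgap1
grin2b
camk2a
syngap1
dlg4
ctnnb1
dlgap2
dlgap3
dlgap4
shank1
shank2
grin1
grin2a
dlg1
dlg2
dlg3
homer2
homer3
abi1
abi2
cttn
actb
arpc2
arpc3
wasf1
baiap2
cyfip1
cyfip2
nckap1
fyn
src
grb2
plcb1
dbnl
cttnbp2
lzts3
sipx0001
sipx0002
sipx0003
sipx0004
sipx0005
sipx0006
sipx0007
sipx0008
sipx0009
sipx0010
sipx0011
sipx0012
sipx0013
sipx0014
sipx0015
sipx0016
sipx0017
sipx0018
sipx0019
sipx0020
sipx0021
sipx0022
sipx0023
sipx0024
sipx0025
sipx0026
sipx0027
sipx0028
sipx0029
sipx0030
sipx0031
sipx0032
sipx0033
sipx0034
sipx0035
sipx0036
sipx0037
sipx0038
sipx0039
sipx0040
sipx0041
sipx0042
sipx0043
sipx0044
sipx0045
sipx0046
sipx0047
sipx0048
sipx0049
sipx0050
sipx0051
sipx0052
sipx0053
sipx0054
sipx0055
sipx0056
sipx0057
sipx0058
sipx0059
sipx0060
sipx0061
sipx0062
sipx0063
sipx0064
sipx0065
sipx0066
sipx0067
sipx0068
sipx0069
sipx0070
sipx0071
sipx0072
sipx0073
sipx0074
sipx0075
sipx0076
sipx0077
sipx0078
sipx0079
sipx0080
sipx0081
sipx0082
sipx0083
sipx0084
sipx0085
sipx0086
sipx0087
sipx0088
sipx0089
sipx0090
sipx0091
sipx0092
sipx0093
sipx0094
sipx0095
sipx0096
sipx0097
sipx0098
sipx0099
sipx0100
sipx0101
sipx0102
sipx0103
sipx0104
sipx0105
sipx0106
sipx0107
sipx0108
sipx0109
sipx0110
sipx0111
sipx0112
sipx0113
sipx0114
sipx0115
sipx0116
sipx0117
sipx0118
sipx0119
sipx0120
sipx0121
sipx0122
sipx0123
sipx0124
sipx0125
sipx0126
sipx0127
sipx0128
sipx0129
sipx0130
sipx0131
sipx0132
sipx0133
sipx0134
sipx0135
sipx0136
sipx0137
sipx0138
sipx0139
sipx0140
sipx0141
sipx0142
sipx0143
sipx0144
sipx0145
sipx0146
sipx0147
sipx0148
sipx0149
sipx0150
sipx0151
sipx0152
sipx0153
sipx0154
sipx0155
sipx0156
sipx0157
sipx0158
sipx0159
sipx0160
sipx0161
sipx0162
sipx0163
sipx0164
sipx0165
sipx0166
sipx0167
sipx0168
sipx0169
sipx0170
sipx0171
sipx0172
sipx0173
sipx0174
sipx0175
sipx0176
sipx0177
sipx0178
sipx0179
sipx0180
sipx0181
sipx0182
sipx0183
sipx0184
sipx0185
sipx0186
sipx0187
sipx0188
sipx0189
sipx0190
sipx0191
sipx0192
sipx0193
sipx0194
sipx0195
sipx0196
sipx0197
sipx0198
sipx0199
sipx0200
sipx0201
sipx0202
sipx0203
sipx0204
sipx0205
sipx0206
sipx0207
sipx0208
sipx0209
sipx0210
sipx0211
sipx0212
sipx0213
sipx0214
sipx0215
sipx0216
sipx0217
sipx0218
sipx0219
sipx0220
sipx0221
sipx0222
sipx0223
sipx0224
sipx0225
sipx0226
sipx0227
sipx0228
sipx0229
sipx0230
sipx0231
sipx0232
sipx0233
sipx0234
sipx0235
sipx0236
sipx0237
sipx0238
sipx0239
sipx0240
sipx0241
sipx0242
sipx0243
sipx0244
sipx0245
sipx0246
sipx0247
sipx0248
sipx0249
sipx0250
sipx0251
sipx0252
sipx0253
sipx0254
sipx0255
sipx0256
sipx0257
sipx0258
sipx0259
sipx0260
sipx0261
sipx0262
sipx0263
sipx0264
sipx0265
sipx0266
sipx0267
sipx0268
sipx0269
sipx0270
sipx0271
sipx0272
sipx0273
sipx0274
sipx0275
sipx0276
sipx0277
sipx0278
sipx0279
sipx0280
sipx0281
sipx0282
sipx0283
sipx0284
sipx0285
sipx0286
sipx0287
sipx0288
sipx0289
sipx0290
sipx0291
sipx0292
sipx0293
sipx0294
sipx0295
sipx0296
sipx0297
sipx0298
sipx0299
sipx0300
sipx0301
sipx0302
sipx0303
sipx0304
sipx0305
sipx0306
sipx0307
sipx0308
sipx0309
sipx0310
sipx0311
sipx0312
sipx0313
sipx0314
sipx0315
sipx0316
sipx0317
sipx0318
sipx0319
sipx0320
sipx0321
sipx0322
sipx0323
sipx0324
sipx0325
sipx0326
sipx0327
sipx0328
sipx0329
sipx0330
sipx0331
sipx0332
sipx0333
sipx0334
sipx0335
sipx0336
sipx0337
sipx0338
sipx0339
sipx0340
sipx0341
sipx0342
sipx0343
sipx0344
sipx0345
sipx0346
sipx0347
sipx0348
sipx0349
sipx0350
sipx0351
sipx0352
sipx0353
sipx0354
sipx0355
sipx0356
sipx0357
sipx0358
sipx0359
sipx0360
sipx0361
sipx0362
sipx0363
sipx0364
sipx0365
sipx0366
sipx0367
sipx0368
sipx0369
sipx0370
sipx0371
sipx0372
sipx0373
sipx0374
sipx0375
sipx0376
sipx0377
sipx0378
sipx0379
sipx0380
sipx0381
sipx0382
sipx0383
sipx0384
sipx0385
sipx0386
sipx0387
sipx0388
sipx0389
sipx0390
sipx0391
sipx0392
sipx0393
sipx0394
sipx0395
sipx0396
sipx0397
sipx0398
sipx0399
sipx0400
sipx0401
sipx0402
sipx0403
sipx0404
sipx0405
sipx0406
sipx0407
sipx0408
sipx0409
sipx0410
sipx0411
sipx0412
sipx0413
sipx0414
sipx0415
sipx0416
sipx0417
sipx0418
sipx0419
sipx0420
sipx0421
sipx0422
sipx0423
sipx0424
sipx0425
sipx0426
sipx0427
sipx0428
sipx0429
sipx0430
sipx0431
sipx0432
sipx0433
sipx0434
sipx0435
sipx0436
sipx0437
sipx0438
sipx0439
sipx0440
sipx0441
sipx0442
sipx0443
sipx0444
sipx0445
sipx0446
sipx0447
sipx0448
sipx0449
sipx0450
sipx0451
sipx0452
sipx0453
sipx0454
sipx0455
sipx0456
sipx0457
sipx0458
sipx0459
sipx0460
sipx0461
sipx0462
sipx0463
sipx0464
sipx0465
sipx0466
sipx0467
sipx0468
sipx0469
sipx0470
sipx0471
sipx0472
sipx0473
sipx0474
sipx0475
sipx0476
sipx0477
sipx0478
sipx0479
sipx0480
sipx0481
sipx0482
sipx0483
sipx0484
sipx0485
sipx0486
sipx0487
sipx0488
sipx0489
sipx0490
sipx0491
sipx0492
sipx0493
sipx0494
sipx0495
sipx0496
sipx0497
sipx0498
sipx0499
sipx0500
sipx0501
sipx0502
sipx0503
sipx0504
sipx0505
sipx0506
sipx0507
sipx0508
sipx0509
sipx0510
sipx0511
sipx0512
sipx0513
sipx0514
sipx0515
sipx0516
sipx0517
sipx0518
sipx0519
sipx0520
sipx0521
sipx0522
sipx0523
sipx0524
sipx0525
sipx0526
sipx0527
sipx0528
sipx0529
sipx0530
sipx0531
sipx0532
sipx0533
sipx0534
sipx0535
sipx0536
sipx0537
sipx0538
sipx0539
sipx0540
sipx0541
sipx0542
sipx0543
sipx0544
sipx0545
sipx0546
sipx0547
sipx0548
sipx0549
sipx0550
sipx0551
sipx0552
sipx0553
sipx0554
sipx0555
sipx0556
sipx0557
sipx0558
sipx0559
sipx0560
sipx0561
sipx0562
sipx0563
sipx0564
sipx0565
sipx0566
sipx0567
sipx0568
sipx0569
sipx0570
sipx0571
sipx0572
sipx0573
sipx0574
sipx0575
sipx0576
sipx0577
sipx0578
sipx0579
sipx0580
sipx0581
sipx0582
sipx0583
sipx0584
sipx0585
sipx0586
sipx0587
sipx0588
sipx0589
sipx0590
sipx0591
sipx0592
sipx0593
sipx0594
sipx0595
sipx0596
sipx0597
sipx0598
sipx0599
sipx0600
sipx0601
sipx0602
sipx0603
sipx0604
sipx0605
sipx0606
sipx0607
sipx0608
sipx0609
sipx0610
sipx0611
sipx0612
sipx0613
sipx0614
sipx0615
sipx0616
sipx0617
sipx0618
sipx0619
sipx0620
sipx0621
sipx0622
sipx0623
sipx0624
sipx0625
sipx0626
sipx0627
sipx0628
sipx0629
sipx0630
sipx0631
sipx0632
sipx0633
sipx0634
sipx0635
sipx0636
sipx0637
sipx0638
sipx0639
sipx0640
sipx0641
sipx0642
sipx0643
sipx0644
sipx0645
sipx0646
sipx0647
sipx0648
sipx0649
sipx0650
sipx0651
sipx0652
sipx0653
sipx0654
sipx0655
sipx0656
sipx0657
sipx0658
sipx0659
sipx0660
sipx0661
sipx0662
sipx0663
sipx0664
sipx0665
sipx0666
sipx0667
sipx0668
sipx0669
sipx0670
sipx0671
sipx0672
sipx0673
sipx0674
sipx0675
sipx0676
sipx0677
sipx0678
sipx0679
sipx0680
sipx0681
sipx0682
sipx0683
sipx0684
sipx0685
sipx0686
sipx0687
sipx0688
sipx0689
sipx0690
sipx0691
sipx0692
sipx0693
sipx0694
sipx0695
sipx0696
sipx0697
sipx0698
sipx0699
sipx0700
sipx0701
sipx0702
sipx0703
sipx0704
sipx0705
sipx0706
sipx0707
sipx0708
sipx0709
sipx0710
sipx0711
sipx0712
sipx0713
sipx0714
sipx0715
sipx0716
sipx0717
sipx0718
sipx0719
sipx0720
sipx0721
sipx0722
sipx0723
sipx0724
sipx0725
sipx0726
sipx0727
sipx0728
sipx0729
sipx0730
sipx0731
sipx0732
sipx0733
sipx0734
sipx0735
sipx0736
sipx0737
sipx0738
sipx0739
sipx0740
sipx0741
sipx0742
sipx0743
sipx0744
sipx0745
sipx0746
sipx0747
sipx0748
sipx0749
sipx0750
sipx0751
sipx0752
sipx0753
sipx0754
sipx0755
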