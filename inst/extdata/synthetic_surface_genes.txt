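G0002
G0015
G0034
G0042
G0064
G0065
G0071
G0076
G0083
G0092
G0094
G0096
G0098
G0102
G0104
G0112
G0128
G0143
G0144
G0146
G0151
G0189
G0192
G0194
G0196
G0209
G0210
G0224
G0228
G0245
G0248
G0250
G0257
G0266
G0267
G0289
G0295
G0298
G0299
G0309
G0311
G0318
G0324
G0325
G0328
G0334
G0339
G0341
G0342
G0363
G0367
G0395
G0409
G0415
G0431
G0445
G0454
G0456
G0459
G0484
G0488
G0489
G0498
G0502
G0506
G0517
G0521
G0524
G0534
G0546
G0554
G0557
G0561
G0562
G0565
G0566
G0574
G0582
G0590
G0598
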