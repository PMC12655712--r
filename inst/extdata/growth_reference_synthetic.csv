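sex,age_days,L,M,S
male,0,0.35,3.35,0.146
male,7,0.3451,3.6055,0.145
male,14,0.3401,3.8618,0.1441
male,21,0.3352,4.1197,0.1431
male,28,0.3303,4.38,0.1422
male,35,0.3254,4.6433,0.1412
male,42,0.3204,4.9062,0.1403
male,49,0.3155,5.1632,0.1393
male,56,0.3106,5.4084,0.1384
male,63,0.3057,5.6362,0.1374
male,70,0.3007,5.8439,0.1365
male,77,0.2958,6.034,0.1355
male,84,0.2909,6.2095,0.1346
male,91,0.2859,6.3732,0.1336
male,98,0.281,6.5279,0.1327
male,105,0.2761,6.6748,0.1317
male,112,0.2712,6.8146,0.1308
male,119,0.2662,6.9481,0.1298
male,126,0.2613,7.0762,0.1289
male,133,0.2564,7.1992,0.1279
male,140,0.2515,7.317,0.1269
male,147,0.2465,7.4297,0.126
male,154,0.2416,7.5371,0.125
male,161,0.2367,7.6396,0.1241
male,168,0.2317,7.7376,0.1231
male,175,0.2268,7.8317,0.1222
male,182,0.2219,7.9224,0.1212
male,189,0.217,8.0102,0.1203
male,196,0.212,8.0959,0.1193
female,0,0.38,3.23,0.142
female,7,0.3747,3.4496,0.1413
female,14,0.3695,3.6696,0.1407
female,21,0.3642,3.8907,0.14
female,28,0.359,4.1133,0.1394
female,35,0.3537,4.3376,0.1387
female,42,0.3485,4.5614,0.1381
female,49,0.3432,4.7804,0.1374
female,56,0.338,4.9905,0.1367
female,63,0.3327,5.1875,0.1361
female,70,0.3274,5.3695,0.1354
female,77,0.3222,5.5382,0.1348
female,84,0.3169,5.6956,0.1341
female,91,0.3117,5.8438,0.1335
female,98,0.3064,5.9847,0.1328
female,105,0.3012,6.1193,0.1321
female,112,0.2959,6.2481,0.1315
female,119,0.2907,6.3718,0.1308
female,126,0.2854,6.4911,0.1302
female,133,0.2801,6.6062,0.1295
female,140,0.2749,6.7171,0.1289
female,147,0.2696,6.8236,0.1282
female,154,0.2644,6.9259,0.1275
female,161,0.2591,7.0238,0.1269
female,168,0.2539,7.1175,0.1262
female,175,0.2486,7.2071,0.1256
female,182,0.2434,7.2928,0.1249
female,189,0.2381,7.3749,0.1243
female,196,0.2328,7.4539,0.1236
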