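RLS2,RSS174,RSS175,dp39,dp12,dp37,dp44,dp7,dp15,dp17
-0.5657,-0.3103,-0.0124,-0.7995,0.374,-0.5728,-0.3565,-0.039,-0.3453,-0.8631
0.321,-1.1941,-0.962,0.3866,1.253,0.9721,0.9844,0.4925,-0.9291,-0.6686
0.1253,0.8716,0.6296,1.2038,1.254,1.8258,-0.4255,1.0496,-0.3039,0.3239
1.3532,0.8151,0.4638,0.4614,-0.1546,1.3047,1.8424,0.4666,0.7638,0.5471
-1.2877,-0.9168,-1.061,-0.9746,0.7146,-0.4974,-0.3726,-0.8674,-0.1493,0.2769
0.3226,1.0321,1.3207,2.0823,0.7554,0.5612,0.1862,2.3107,0.873,1.1616
0.2669,-0.625,-0.1522,-0.5263,-0.5805,-0.7172,0.1156,-0.6055,-0.5009,-0.7561
0.3997,0.7238,0.828,-0.0764,0.0118,0.2801,0.8201,1.0797,0.6051,0.1228
0.4588,0.4644,0.7769,0.1856,-1.4539,0.6898,1.0794,0.4689,0.3882,0.234
2.1502,0.096,0.066,-0.7427,0.211,-1.7627,1.3825,-0.3037,-0.3287,-0.2155
1.0862,0.1858,0.1097,-0.9399,1.3328,-0.4795,0.8627,0.1092,-0.3411,-1.0726
0.0369,0.2958,0.0413,0.1901,0.3135,0.2711,0.8073,0.909,0.2148,0.2347
0.3879,0.5946,0.0985,-0.5769,-0.4901,0.9832,-1.7005,0.5578,-1.4632,-0.5411
-0.1444,-0.7785,-1.5754,-0.0922,-0.179,-0.3421,0.3959,0.5826,-0.2532,-0.1759
-0.7208,-1.5895,-1.4818,-0.6208,-2.7957,-0.5637,-0.5114,0.107,-0.4147,-0.7535
0.9193,-0.0698,0.202,0.8505,0.9324,-0.5007,0.9084,1.2091,0.8833,1.4024
-0.1654,0.0236,0.1974,1.9109,0.4101,-1.1203,-0.9274,2.1307,2.6513,2.0896
1.8384,3.0541,2.511,2.8864,0.3559,1.7662,-0.5082,2.999,0.998,1.4898
0.1406,-0.8368,-0.8626,0.5903,0.3541,-0.3918,-0.5826,0.697,1.1974,0.9722
0.6643,-0.651,-0.94,-0.6436,-0.7085,-0.9661,1.1875,-0.459,-0.5765,-0.3276
0.1074,1.5303,1.7594,1.6678,0.6568,0.9824,0.3438,0.31,1.1403,0.7502
1.0787,-0.9446,-1.0674,-1.3155,-0.7144,-1.1408,1.0256,-1.3764,-0.8419,-0.5219
1.4301,-1.7955,-1.7916,-1.5475,-0.8423,-1.2492,0.9395,-1.8659,-1.1842,-0.9283
-0.3076,-0.1034,-0.1351,1.1351,0.9062,-0.4684,-0.1034,1.4993,0.5447,0.173
0.079,-0.0719,-0.0288,1.3563,0.3194,-0.0589,0.0076,1.5744,2.5115,2.1747
2.4866,-1.8824,-1.8157,-2.4479,-1.9201,-1.408,1.3134,-2.4064,-2.7218,-2.2061
2.0744,0.3841,0.4288,-0.0228,0.7173,-0.1025,1.1518,1.2584,0.1065,-0.0195
0.3312,2.5089,2.72,0.692,2.9463,1.2871,0.8398,0.7263,0.305,0.2084
-1.2527,0.263,0.1311,0.3697,-0.9362,-0.3153,-1.2956,-0.0195,1.1037,0.8344
1.3364,1.3887,1.7861,1.3085,1.0307,1.3477,-0.3216,1.2724,1.0781,0.8842
0.7971,0.1195,0.5272,-0.2659,0.6517,1.7999,0.3239,-0.068,0.4732,0.0174
0.2261,0.5851,0.553,0.477,1.3564,0.6066,-0.2366,0.5344,-0.6657,-0.0299
0.5007,-2.3768,-2.2878,-0.853,-2.0089,-1.6383,-0.8683,-0.773,-2.2415,-1.7382
-1.4468,0.6766,0.53,1.6818,0.2295,-0.0266,0.1595,2.7112,0.6375,0.3537
-0.1484,-0.7026,-0.8415,-1.1755,-0.1436,-1.5356,-1.0251,-0.0659,-0.8471,-1.5257
0.1713,-2.6247,-2.4033,-1.7943,-1.6563,-0.2693,0.934,-1.3837,-1.8347,-1.7918
0.8581,-0.683,-1.2041,-1.8116,1.6657,-1.2059,-1.0854,-2.0001,-1.9378,-2.2503
0.5021,0.1222,1.1095,0.4778,-0.6332,0.4482,-1.077,-0.603,-0.138,0.1588
-0.2796,0.6663,0.3408,1.8773,-0.2298,0.4734,-0.712,-0.1494,1.4979,1.3984
-1.0923,0.7297,1.0572,1.7222,-0.9505,1.991,-0.7612,1.3582,1.7794,2.2446
-1.0673,-0.127,-0.3338,0.6527,0.8284,-0.831,-0.3263,-0.0665,1.2338,0.5504
0.9796,-3.5005,-2.7116,-1.9412,-0.4889,-2.5735,0.8319,-1.0872,-1.1765,-1.514
-0.0836,-0.6876,-0.7324,0.6126,-0.5418,-0.7823,0.0314,-0.3641,-0.7182,-0.5775
-0.2956,0.7192,0.5969,0.0175,0.6795,1.0392,0.0852,-0.285,-0.2374,-0.215
-0.7435,1.2887,1.3544,0.3082,1.0649,0.4384,-0.0648,1.4685,1.1582,0.7435
0.2158,1.3191,1.0636,1.454,0.8054,1.1191,1.5471,0.8534,3.0223,2.0975
-1.7919,0.5437,0.9219,0.43120000000000003,0.4478,1.31,-1.5816,1.4097,0.9687,0.7791
0.0313,-1.0837,-1.3686,-0.7179,-0.568,0.3742,-0.7461,-0.4096,-0.3903,-0.1963
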