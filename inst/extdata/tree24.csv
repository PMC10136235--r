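# synthetic arterial tree (non-anatomical), 24 segments
# generated by stenosim::synthetic_tree(24, seed = 7)
id,parent_id,length_cm,area_prox_cm2,area_dist_cm2,p0_mmhg,p1_mmhg,visc_coeff,terminal_r1,terminal_r2,terminal_ct
1,0,4.187229526,5.436661392,5.060163284,80,99.52682537,0,,,
2,1,2.929046241,4.817715116,4.635521346,80,104.6662231,0,,,
3,2,2.958630341,4.365185217,4.028773689,80,109.8870965,0,,,
4,3,4.958940224,3.8452398,3.399478609,80,120.5826483,0,,,
5,4,9.80773761,3.137699091,2.619162225,80,143.0362412,0,,,
6,5,4.906163705,2.386785444,2.172938927,80,173.1855932,0,,,
7,6,8.120602318,1.965467558,1.724786123,80,199.0230425,0,,,
8,7,5.985981774,1.623164827,1.312567294,80,226.4155617,0,,,
9,1,3.510702364,1.20265861,1.066042096,80,137.2867192,0,,,
10,9,18.80591259,0.4992159477,0.4025541221,80,199.0230425,0,1.283787444,11.06582219,0.02421205004
11,9,45.32243729,0.4462314545,0.351163871,80,233.5087423,0,1.584864938,12.57201928,0.02112112819
12,2,19.00508915,0.4944102217,0.3928651387,80,199.0230425,0,1.315448678,11.33873153,0.02362929573
13,3,3.663401206,0.8161204844,0.7010700176,80,166.9665372,0,,,
14,13,45.29256543,0.4401629422,0.351115862,80,233.5087423,0,1.585081641,12.57373829,0.02111824063
15,4,6.231897185,0.3988633155,0.3538264852,80,233.5087423,0,1.572938516,12.47741235,0.02128127398
16,5,5.04698746,0.6037918705,0.5070979831,80,219.420632,0,1.066156784,8.737444155,0.03049995284
17,5,6.875979696,0.5635687261,0.4528798985,80,219.420632,0,1.193795434,9.783477525,0.02723894791
18,6,3.975489142,0.4437499558,0.4089731651,80,270.454852,0,1.45804355,10.69773264,0.02459813027
19,6,3.999614225,0.4474384238,0.406200805,80,270.454852,0,1.467994839,10.77074571,0.0244313837
20,7,7.139719087,0.2922329976,0.255834408,80,309.8811334,0,2.486194369,16.94585272,0.01538743525
21,8,9.152431526,0.59532615,0.5127671115,80,309.8811334,0,,,
22,8,9.127861268,0.5952009758,0.5070555525,80,309.8811334,0,,,
23,21,43.11146249,0.4109513751,0.3227808271,80,396.2226061,0,2.216862845,13.18487681,0.01941399953
24,22,40.85011735,0.4047575912,0.3141494919,80,396.2226061,0,2.277771702,13.54713457,0.0188948586
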