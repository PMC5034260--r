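day,f_pi,f_ai
0,0.15,0.7
0.25,0.150498031682632,0.7291796875
0.5,0.151937286926743,0.7521875
0.75,0.154235506026655,0.7697265625
1,0.157310429276689,0.7825
1.25,0.161079796971168,0.7912109375
1.5,0.165461349404413,0.7965625
1.75,0.170372826870746,0.7992578125
2,0.17573196966449,0.8
2.25,0.181456518079965,0.79219836529834
2.5,0.187464212411494,0.770494055630328
2.75,0.193672792953398,0.737437962651413
3,0.2,0.695580978017048
3.25,0.208301915495121,0.647473993382683
3.5,0.220117019971505,0.595667900403769
3.75,0.234886651606853,0.542713590735756
4,0.25205214857887,0.491161956034096
4.25,0.271054849065258,0.44356388795424
4.5,0.29133609124372,0.402470278151638
4.75,0.31233721329196,0.370432018281741
5,0.333499553387681,0.35
5.25,0.354264449708586,0.336537393657911
5.5,0.374073240432378,0.323716736793932
5.75,0.39236726373676,0.311552971843957
6,0.408587857799435,0.300061041243877
6.25,0.422176360798106,0.289255887429587
6.5,0.432574110910478,0.27915245283698
6.75,0.439222446314251,0.269765679901949
7,0.441562705187131,0.261110511060388
7.25,0.440133967552275,0.25320188874819
7.5,0.436060456865768,0.246054755401248
7.75,0.429661226454695,0.239684053455455
8,0.421255329646144,0.234104725346705
8.25,0.411161819767202,0.229331713510891
8.5,0.399699750144957,0.225379960383907
8.75,0.387188174106495,0.222264408401645
9,0.373946144978905,0.22
9.25,0.360292716089272,0.218199945141066
9.5,0.346546940764685,0.216469153605016
9.75,0.333027872332231,0.214810117554859
10,0.320054564118996,0.213225329153605
10.25,0.307946069452068,0.211717280564263
10.5,0.297021441658535,0.210288463949843
10.75,0.287599734065483,0.208941371473354
11,0.28,0.207678495297806
11.25,0.273288403199215,0.206502327586207
11.5,0.266413338621292,0.205415360501567
11.75,0.25951720642487,0.204420086206897
12,0.252742406768587,0.203518996865204
12.25,0.246231339811083,0.202714584639498
12.5,0.240126405710996,0.20200934169279
12.75,0.234570004626964,0.201405760188088
13,0.229704536717627,0.200906332288401
13.25,0.225672402141623,0.20051355015674
13.5,0.222616001057592,0.200229905956113
13.75,0.220677733624171,0.20005789184953
14,0.22,0.2
14.25,0.221481581834725,0.201034937553833
14.5,0.225715853136373,0.20401593453919
14.75,0.232387102601156,0.20875726744186
15,0.241179618925284,0.215073212747631
15.25,0.251777690804967,0.222778046942291
15.5,0.263865606936416,0.231686046511628
15.75,0.277127656015842,0.24161148794143
16,0.291248126739456,0.252368647717485
16.25,0.305911307803468,0.263771802325581
16.5,0.320801487904089,0.275635228251507
16.75,0.335602955737529,0.287773201981051
17,0.35,0.3
17.25,0.365529191910042,0.313758175872093
17.5,0.383772582112944,0.330414244186046
17.75,0.404482678445036,0.349668422965116
18,0.427411988742648,0.371220930232558
18.25,0.452313020842111,0.394771984011628
18.5,0.478938282579754,0.420021802325581
18.75,0.507040281791908,0.446670603197674
19,0.536371526314902,0.474418604651163
19.25,0.566684523985069,0.502966024709302
19.5,0.597731782638737,0.532013081395349
19.75,0.629265810112236,0.561259992732558
20,0.661039114241898,0.590406976744186
20.25,0.692804202864052,0.619154251453488
20.5,0.724313583815029,0.647202034883721
20.75,0.755319764931158,0.67425054505814
21,0.785575254048771,0.7
21.25,0.814832559004196,0.726909722222222
21.5,0.842844187633765,0.756944444444444
21.75,0.869362647773808,0.7890625
22,0.894140447260655,0.822222222222222
22.25,0.916930093930636,0.855381944444444
22.5,0.937484095620081,0.8875
22.75,0.955554960165321,0.917534722222222
23,0.970895195402686,0.944444444444444
23.25,0.983257309168507,0.9671875
23.5,0.992393809299112,0.984722222222222
23.75,0.998057203630833,0.996006944444444
24,1,1
24.25,0.995193441812094,0.9991943359375
24.5,0.981170099431818,0.9966796875
24.75,0.958524471134334,0.9923095703125
25,0.927851055194805,0.9859375
25.25,0.889744349888393,0.9774169921875
25.5,0.84479885349026,0.9666015625
25.75,0.793609064275568,0.9533447265625
26,0.736769480519481,0.9375
26.25,0.674874600497159,0.9189208984375
26.5,0.608518922483766,0.8974609375
26.75,0.538296944754464,0.8729736328125
27,0.464803165584416,0.8453125
27.25,0.388632083248783,0.8143310546875
27.5,0.310378196022727,0.7798828125
27.75,0.230636002181412,0.7418212890625
28,0.15,0.7
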