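run,iteration,cells
1,0,1
1,2,1
1,4,1.0000000034254701
1,6,1.0001014939144024
1,8,1.0189193240637933
1,10,1.30206588233932
1,12,2.741792227906522
1,14,7.313842062658628
1,16,16.5726094535212
1,18,28.308801229670657
1,20,38.56667615351653
1,22,45.59829971024839
1,24,49.782670513124955
1,26,52.087913363376245
1,28,53.307399846880344
1,30,53.93912641956212
1,32,54.262883452757
1,34,54.42790265908707
1,36,54.51177969730869
1,38,54.55435319162756
1,40,54.57594678547116
1,42,54.586895246950974
1,44,54.59244535501285
1,46,54.595258611463144
1,48,54.59668453651838
1,50,54.597407262525444
1,52,54.59777356967691
1,54,54.59795922800796
1,56,54.59805332638507
1,58,54.59810101878077
1,60,54.59812519095948
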