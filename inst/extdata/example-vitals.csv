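time_s,etco2_mmhg,rr_bpm,spo2_pct,pr_bpm
0,37.4851006625256,14.4397359144995,97.955202969076,70.0276181996971
1,37.079918256319,13.326717004302,97.1823930868799,71.2102895678825
2,35.4696160500664,14.0263983485615,97.0293909179747,74.6170306110581
3,37.0808217337731,14.4193197663491,97.9073092957733,73.909520023419
4,38.1145370480661,12.6179167105632,98.6375999903898,67.7338423380639
5,37.0208238106511,13.777708378599,97.5112897798128,74.1379394522514
6,36.2838603129018,14.2886627549552,96.9299620910415,69.3850421742449
7,41.2894069586402,13.5272700466503,96.2437095235535,73.0945198259116
8,38.5963651990443,14.7804724438537,96.8320861039664,69.9740385813099
9,37.9008833996967,12.8434000400963,97.7112853190704,73.5602696676312
10,37.1770601947085,14.236165419693,96.9694070626231,72.1806913842357
11,37.9291602508342,14.4438017812521,98.5391041637512,70.2031758874137
12,36.3035477857983,13.6010915652202,98.551401652577,72.3653121567538
13,39.740548998982,14.1565870693134,96.7104351445588,70.9778361354121
14,40.4042036183351,13.6355675624544,96.83167901458,74.4894668795794
15,38.6776180611982,13.709715624893,97.7605175173619,71.1691615188618
16,36.0703884047,13.8745492930138,98.1768907301911,73.6790726232907
17,35.7973224397392,13.3877988854648,97.3600851003257,75.792598965397
18,39.8966654847473,13.0671861130017,96.9558556051668,71.1380007106426
19,38.399032151731,13.7412594575778,97.628179588406,71.7778371732963
20,38.2254284144726,13.720058119575,97.0100768339723,72.2430120576426
21,36.810086449934,13.5304822910227,96.644238801431,74.3692111091726
22,39.5309196954024,12.7280978811562,97.1665996408359,72.9709101690505
23,41.1633851735949,15.3516476435825,97.2020962109487,68.5505923081512
24,41.1711012278972,14.4508669124425,97.0708015925934,73.0083114505542
25,41.915917865895,16.1341067128529,97.9399439546518,72.4514328874988
26,37.6549704428393,14.2852279601652,98.4516662178404,69.996420821166
27,38.9305507881998,13.7103036865129,97.2176366840966,72.8561092030677
28,39.5978096625799,14.4549970616994,97.4712467133613,71.1983971096386
29,39.7706955883261,14.0229396286453,97.242570517494,70.7886247121162
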