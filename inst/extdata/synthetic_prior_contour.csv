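"x","y"
-0.0669449254619515,140.662768222271
-3.18976930833057,140.340457835579
-6.20288172329334,139.459031359912
-9.03696594989554,138.108568637185
-11.6663838555186,136.393323155637
-14.0918535709311,134.400051342646
-16.3273505585097,132.195806384328
-18.3920561011752,129.830809489794
-20.3050623680394,127.341496291181
-22.0842802885572,124.754858958963
-23.7445015106284,122.090276564104
-25.2979692894474,119.362074264805
-26.753686843094,116.580482709904
-28.1229175201021,113.755313431963
-29.4129288908787,110.893102482512
-30.6300923020239,107.999160752228
-31.779143449353,105.077505166332
-32.8655753678553,102.131990151338
-33.8935943823584,99.1655828402824
-34.8667606587108,96.1807302828027
-35.7882814925095,93.1795308109854
-36.6608000381208,90.163720537834
-37.486826332046,87.1348458574907
-38.2685042780758,84.0942239204838
-39.0078927257918,81.0430425722341
-39.7066076768536,77.9822908931991
-40.3655227323264,74.9127249552797
-40.9869564258879,71.835351949161
-41.5711246465879,68.7506878828926
-42.1195048943749,65.6594608823732
-42.6328622422591,62.5622250465875
-43.1119132676341,59.459497858667
-43.5573072244404,56.351760677852
-43.9694264373658,53.2394361303004
-44.3485677323052,50.1229223529923
-44.6952589356127,47.0026321084254
-45.0094981412586,43.8789068523816
-45.2912934969651,40.7520878797533
-45.5407247129872,37.6225209217445
-45.7577134393616,34.4905373758288
-45.9419512868231,31.3564567765764
-46.093355674225,28.2206185670328
-46.2117128198207,25.0833592650496
-46.2968474241348,21.9450227249912
-46.3489863589745,18.8059646579581
-46.3685246557007,15.6665344226509
-46.3564694156719,12.5270665269285
-46.3144122435829,9.38785717611968
-46.2448685911449,6.24913639732296
-46.1512467041419,3.11104146892344
-46.0378004925848,-0.0263994049451144
-45.9093070721938,-3.16326011918707
-45.7705449173907,-6.29968341481347
-45.625708646041,-9.43583211604825
-45.4777776426345,-12.5718363767018
-45.3280964875525,-15.7077575933244
-45.1763131780893,-18.8435777647474
-45.0205823193259,-21.9792043662756
-44.857958400778,-25.1144810120847
-44.684915708126,-28.2491998554904
-44.4977679318445,-31.3831081899933
-44.2930109662355,-34.5159152405603
-44.0675743008674,-37.647302062439
-43.8188288613096,-40.7769235297475
-43.5446663906733,-43.9044208533787
-43.243406865506,-47.0294243826451
-42.9136537333187,-50.1515497882409
-42.5544686381498,-53.2704262073173
-42.1648583934716,-56.385648151046
-41.7440783595782,-59.4968131965894
-41.2912827368018,-62.6034801798113
-40.8057197201258,-65.7051945472053
-40.2866440049758,-68.8014767829206
-39.7330492241785,-71.8917738316237
-39.1439710961951,-74.9755036706389
-38.5181337600487,-78.0519838062132
-37.854254292828,-81.1204795358781
-37.1512307314089,-84.1802441441705
-36.4067909104309,-87.2301966347872
-35.6195277924028,-90.2693769572165
-34.7871869842992,-93.2965221689009
-33.9071985113004,-96.3101609197889
-32.9768549213755,-99.3086368243218
-31.9930348304057,-102.289994463527
-30.9520906123548,-105.251890550269
-29.849967738554,-108.191570111808
-28.6816502134711,-111.105574482688
-27.441681170891,-113.989817858616
-26.1234659652908,-116.839148659223
-24.7189683045305,-119.646951305074
-23.2190490425155,-122.404958002075
-21.6130453579697,-125.10256734588
-19.8879473210593,-127.725611238077
-18.0282811587107,-130.255024738151
-16.0158811620332,-132.664690632987
-13.8277847030152,-134.916001084823
-11.4431319060121,-136.957933454958
-8.84644963322775,-138.722347218006
-6.02781281830234,-140.104729808394
-3.01818371523767,-140.99789781631
0.107170438657278,-141.294481239719
3.22893891906996,-140.962399926366
6.22819280466962,-140.03504975781
9.03498681521167,-138.628832477365
11.6203966129538,-136.847979508004
13.995665190603,-134.795167896469
16.1745360216907,-132.53494607096
18.1796908849747,-130.119261092349
20.0328534244766,-127.585088056269
21.7522641184997,-124.958319207868
23.3532066897745,-122.257708061094
24.848535600824,-119.497213511796
26.2490007670798,-116.687400214369
27.5633782952209,-113.836299301049
28.7995401211504,-110.950423915772
29.96391989198,-108.034845273877
31.0621962909793,-105.093727669425
32.0991872710259,-102.130446206919
33.0788005495604,-99.1477044875293
34.0048249356328,-96.1478925880836
34.8803130423149,-93.1329440209632
35.7076937412956,-90.1044399232984
36.4895925001789,-87.0638755853384
37.2282484865917,-84.0125176342012
37.925151960927,-80.951353713212
38.5823648364586,-77.8814236105022
39.2010928864245,-74.8035061699574
39.7826052538992,-71.7183410123312
40.3281220327478,-68.6266080720266
40.838769227471,-65.5289249110867
41.3155866285146,-62.4258543347217
41.7594085327126,-59.3178928938333
42.1713201672252,-56.2055414805039
42.5522725953527,-53.0892491149945
42.903390927786,-49.969454383787
43.2260538371904,-46.8465883496499
43.5216530799637,-43.7210443736981
43.7920424802579,-40.5932186004679
44.0393089964557,-37.463479917628
44.2660401389835,-34.3321865196746
44.4749792368804,-31.1996555688317
44.6691706578242,-28.0661757684446
44.8516725306132,-24.9319933863525
45.0252509491198,-21.7973041251704
45.1920689338389,-18.6622478208697
45.353317150946,-15.5269001066538
45.5089719098443,-12.3912697314264
45.6577359853703,-9.25530489645413
45.7971422285428,-6.11891015158253
45.9239765206259,-2.98198187470561
46.0347601907519,0.155554220836987
46.126194778984,3.29371376121646
46.1955321269975,6.43243925852278
46.2406104960869,9.57160686134405
46.2599030892081,12.7110388224955
46.2523200533115,15.8505209065168
46.2171434870086,18.989815084269
46.1537523804731,22.128666309507
46.061694652026,25.2668076350604
45.9404950844757,28.4039586459301
45.7898188087545,31.5398321570457
45.6091880816073,34.67412295421
45.3982410955599,37.80651943359
45.1564695516658,40.9366875866753
44.8835749611095,44.0642960041794
44.5790609765837,47.1889842781512
44.2424992382878,50.3103832383167
43.8734282507715,53.4281054133875
43.4712766146319,56.541733309935
43.0354917364825,59.6508321839492
42.5654894287947,62.7549426422928
42.0605938694544,65.8535687884402
41.519938376002,68.9461558481872
40.9427449380693,72.0321322546438
40.3277095932828,75.1107900138665
39.6741249147793,78.1814949301713
38.9806737916868,81.2434430868014
38.2452934861368,84.2955924748268
37.4668764918686,87.3370504138317
36.64361537436,90.366677387711
35.7731875741866,93.3830912685227
34.8532653460938,96.3847806314927
33.8809099458872,99.3698969106711
32.8530728461729,102.336366728764
31.7658959272583,105.281606286138
30.6154912681987,108.20272865872
29.3968093514438,111.096030779249
28.1040404863757,113.95699675746
26.7314693576424,116.780544242871
25.270995258123,119.559640932562
23.7138122490581,122.28572470678
22.048216132269,124.946950725698
20.2612464078997,127.528239205729
18.3387533667704,130.010234417843
16.2638879351205,132.366325774105
14.0168253774634,134.558783545435
11.5787108100015,136.536574695391
8.93421871153867,138.228490401781
6.08493448771721,139.546577212102
3.06040869794828,140.387971354364
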