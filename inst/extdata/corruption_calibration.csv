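# Monte-Carlo calibration grid for corrupt_string(): mean scored
# accuracy of corrupt_once productions of random targets, by target
# length and noise rate.  Regenerate with build_corruption_calibration()
# (internal seed 20150609, 400 draws per cell).
length,rate,mean_accuracy
2,0,1
2,0.1,0.943551960784314
2,0.2,0.897431699346405
2,0.3,0.852569934640523
2,0.4,0.789621241830065
2,0.5,0.751267647058824
2,0.6,0.699805882352941
2,0.7,0.65293660130719
2,0.8,0.621682026143791
2,0.9,0.563733006535948
2,1,0.55640522875817
3,0,1
3,0.1,0.951010620915033
3,0.2,0.896753594771242
3,0.3,0.855952418300654
3,0.4,0.794985522875817
3,0.5,0.737142091503268
3,0.6,0.699277091503268
3,0.7,0.662345653594771
3,0.8,0.623855196078431
3,0.9,0.59119660130719
3,1,0.532482320261438
4,0,1
4,0.1,0.944148431372549
4,0.2,0.876637843137255
4,0.3,0.841763529411765
4,0.4,0.785294607843137
4,0.5,0.755005490196078
4,0.6,0.703087717086835
4,0.7,0.66737908496732
4,0.8,0.634357516339869
4,0.9,0.582002156862745
4,1,0.56041370681606
5,0,1
5,0.1,0.94492045751634
5,0.2,0.893253361344538
5,0.3,0.840731743697479
5,0.4,0.790749327731092
5,0.5,0.74975578898226
5,0.6,0.691686157018363
5,0.7,0.668760667600373
5,0.8,0.620562544351074
5,0.9,0.599006444911298
5,1,0.558781918767507
6,0,1
6,0.1,0.93386451914099
6,0.2,0.891103711484594
6,0.3,0.843729691876751
6,0.4,0.798883426704015
6,0.5,0.757110768751945
6,0.6,0.70921364379085
6,0.7,0.672785683162154
6,0.8,0.63080320183629
6,0.9,0.59449417211329
6,1,0.564667134298164
7,0,1
7,0.1,0.936982469654528
7,0.2,0.883447218331777
7,0.3,0.83426589091192
7,0.4,0.792165499533147
7,0.5,0.739508252412076
7,0.6,0.706131543516397
7,0.7,0.666475668802875
7,0.8,0.626381658885777
7,0.9,0.595893506069094
7,1,0.557755341581077
8,0,1
8,0.1,0.942284150326797
8,0.2,0.889486176470588
8,0.3,0.840248915626857
8,0.4,0.798847075163399
8,0.5,0.748545884828679
8,0.6,0.710870766983561
8,0.7,0.67800047781739
8,0.8,0.644337140522876
8,0.9,0.595256697365815
8,1,0.56675855862547
9,0,1
9,0.1,0.947631946920182
9,0.2,0.89107660724896
9,0.3,0.845088930481283
9,0.4,0.791646810259457
9,0.5,0.755396229413288
9,0.6,0.708183512576748
9,0.7,0.672482524643113
9,0.8,0.640899654006125
9,0.9,0.598432469491293
9,1,0.566046832405068
10,0,1
10,0.1,0.944170802139037
10,0.2,0.893861663695781
10,0.3,0.842345371817725
10,0.4,0.798392779606015
10,0.5,0.749659158782394
10,0.6,0.718593139083139
10,0.7,0.669842411216235
10,0.8,0.633014578885167
10,0.9,0.607920391014215
10,1,0.566981919648978
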