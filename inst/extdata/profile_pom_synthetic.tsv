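depth_bin_center	value
12.5	0.116356454382007
37.5	0.141900815174475
62.5	0.122987173230663
87.5	0.081270475202188
112.5	0.0372148259829816
137.5	0.0133511177944493
162.5	0.00326823295795436
187.5	0.000660509524555199
212.5	8.77959913633812e-05
237.5	8.53827479105824e-06
262.5	6.56646389421381e-07
287.5	3.92282767226025e-08
312.5	1.64536914814176e-09
337.5	9.09828582917919e-10
362.5	9.63210099382600e-09
387.5	1.07127417773722e-07
412.5	8.43565789239171e-07
437.5	5.32309235482604e-06
462.5	3.37962034046707e-05
487.5	0.000159407622916381
512.5	0.00066630789148096
537.5	0.00220770598179273
562.5	0.00600759269457114
587.5	0.014109129477515
612.5	0.0290677225398189
637.5	0.0497453804103943
662.5	0.0708618813549938
687.5	0.0792706264309161
712.5	0.0760803342444905
737.5	0.0734461952081889
762.5	0.0518306142497349
787.5	0.0294003853268273
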