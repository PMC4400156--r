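# ploidycall error model
# model_kind	full
# nqs_bin	0.1
section	true_nt	gg	q	obs_nt	alpha	beta	gamma	prob
coef	A	0	0	.	-5.9428175882493095	3.0004164882059041	0.48708564703444329	.
coef	A	0	1	.	-0.3033186555061021	0	0.73396750060864291	.
coef	A	1	0	.	-6.8114854267070752	3.0243723803065392	0.60744805643816535	.
coef	A	1	1	.	0.80523318518852893	0	0.29120258244150299	.
coef	C	0	0	.	-5.8813891627944299	2.9981218342802158	0.50108311688563578	.
coef	C	0	1	.	-0.45366640674664327	0	0.81118276580439586	.
coef	C	1	0	.	-6.666397591073256	2.9885938622245303	0.62630830013694183	.
coef	C	1	1	.	-1.1470424204130876	0	0.88896152525829819	.
coef	G	0	0	.	-6.3169564820645778	2.9907243326918511	0.56108229054777958	.
coef	G	0	1	.	-0.36767847749312182	0	0.70804666868865185	.
coef	G	1	0	.	-6.0022355109630983	2.9492467085508984	0.38441539014570969	.
coef	G	1	1	.	0.26132231621332852	0	0.40677774188660465	.
coef	T	0	0	.	-5.7812695362204414	2.988841997984319	0.46303028423953574	.
coef	T	0	1	.	-0.27036031123975984	0	0.7384510182760925	.
coef	T	1	0	.	-7.9419790741613001	3.0501855190208826	0.91620921488062845	.
coef	T	1	1	.	-1.7380387129803474	0	1.0488063005089077	.
sub	A	0	.	A	.	.	.	0
sub	A	0	.	C	.	.	.	0.22162995742398336
sub	A	0	.	G	.	.	.	0.50095544604244191
sub	A	0	.	T	.	.	.	0.2774145965335747
sub	A	1	.	A	.	.	.	0
sub	A	1	.	C	.	.	.	0.22186948853615521
sub	A	1	.	G	.	.	.	0.50546737213403881
sub	A	1	.	T	.	.	.	0.27266313932980601
sub	C	0	.	A	.	.	.	0.23590291333652535
sub	C	0	.	C	.	.	.	0
sub	C	0	.	G	.	.	.	0.26566240654119555
sub	C	0	.	T	.	.	.	0.49843468012227909
sub	C	1	.	A	.	.	.	0.23228495642288746
sub	C	1	.	C	.	.	.	0
sub	C	1	.	G	.	.	.	0.2625994694960212
sub	C	1	.	T	.	.	.	0.50511557408109131
sub	G	0	.	A	.	.	.	0.49491682070240295
sub	G	0	.	C	.	.	.	0.26270794824399263
sub	G	0	.	G	.	.	.	0
sub	G	0	.	T	.	.	.	0.24237523105360442
sub	G	1	.	A	.	.	.	0.50520514390691973
sub	G	1	.	C	.	.	.	0.25107164727495407
sub	G	1	.	G	.	.	.	0
sub	G	1	.	T	.	.	.	0.24372320881812615
sub	T	0	.	A	.	.	.	0.28291777559882336
sub	T	0	.	C	.	.	.	0.49831909230984733
sub	T	0	.	G	.	.	.	0.2187631320913293
sub	T	0	.	T	.	.	.	0
sub	T	1	.	A	.	.	.	0.27753779697624192
sub	T	1	.	C	.	.	.	0.49892008639308855
sub	T	1	.	G	.	.	.	0.22354211663066956
sub	T	1	.	T	.	.	.	0
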