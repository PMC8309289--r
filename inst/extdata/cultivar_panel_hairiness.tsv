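cultivar	phenotype	genotype
Zhongyou No. 4	Non-hairy	T/T
Baihuashanbitao	Hairy	G/G
10-7	Hairy	T/G
96-51	Hairy	T/G
Bairuyu	Hairy	G/G
ludong-2-04	Non-hairy	T/T
P7-12-03	Non-hairy	T/T
Shanza-02	Hairy	T/G
Shuipingzhi	Hairy	T/G
Weni2	Hairy	G/G
yb144	Hairy	T/G
Zhongpan No. 01	Hairy	T/G
Zhongtao No. 05	Hairy	T/G
Zhongyou No. 08	Non-hairy	T/T
Zhongyou No. 13	Non-hairy	T/T
Zhongyou No. 20	Non-hairy	T/T
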