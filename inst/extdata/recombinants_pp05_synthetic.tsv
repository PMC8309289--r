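individual	phenotype	Pp05-SNP-14562747	Pp05-SNP-15464780	Pp05-SNP-15760886	Pp05-SNP-15858687	Pp05-SNP-15959172	Pp05-SNP-16242580	Pp05-SNP-16563677
Zhongyou No. 4	non-hairy	a	a	a	a	a	a	a
Baihuashanbitao	hairy	h	h	h	h	h	h	h
REC01	hairy	a	a	a	h	h	h	h
REC02	hairy	a	a	h	h	h	h	h
REC03	non-hairy	h	a	a	a	a	a	a
REC04	non-hairy	h	h	a	a	a	a	a
REC05	hairy	h	h	h	h	h	h	a
REC06	hairy	h	h	h	h	h	a	a
REC07	non-hairy	a	a	a	a	a	h	h
REC08	non-hairy	a	a	a	a	a	a	h
REC09	hairy	a	h	h	h	h	h	h
REC10	non-hairy	h	a	a	a	a	a	h
NONREC01	hairy	h	h	h	h	h	h	h
NONREC02	non-hairy	a	a	a	a	a	a	a
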