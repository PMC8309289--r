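marker	chrom	pos	allele_recurrent	allele_nonrecurrent
Pp05-SNP-14562747	Pp05	14562747	G	T
Pp05-SNP-15464780	Pp05	15464780	C	T
Pp05-SNP-15760886	Pp05	15760886	C	T
Pp05-SNP-15858687	Pp05	15858687	A	G
Pp05-SNP-15959172	Pp05	15959172	C	T
Pp05-SNP-16242580	Pp05	16242580	C	G
Pp05-SNP-16563677	Pp05	16563677	T	C
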