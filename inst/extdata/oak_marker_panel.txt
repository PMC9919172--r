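# oakdiff marker panel, format v1
marker	QP_miSeq14a
number	14
method	caps
strand	+
fwd	TGTTGACCAAAATGGATAAGAATT
rev	GTTTGTCTGTCTTGAATGGCC
enzyme	MboI
expected_len	robur=187,petraea=187
fragments	robur=187;petraea=80,107
gene	LOC115972447 (protein detoxification 56-like)
locus	QP_miSeq14a_SNP1	Chr9	45479689	T	C	T	C	84
locus	QP_miSeq14a_SNP2	Chr9	45479691	C	T	C	T	86
marker	QP_miSeq32
number	32
method	fragment_size
strand	+
fwd	TGAGGGGAAATCACAATTATGTC
rev	TGATGTTCTGTTCTGATGAATGAC
expected_len	robur=188,petraea=193
fragments	robur=188;petraea=193
gene	LOC115974824 (RRC1 isoform X1/X2)
locus	QP_miSeq32	Chr7	38644432	-	GCTTC	188	193	100
marker	QP_miSeq36
number	36
method	caps
strand	-
fwd	TCACTTGTTCTATTTGCAACATAT
rev	TATTCTGTGTCTGAGTAGGTGATAC
enzyme	MseI
expected_len	robur=169,petraea=169
fragments	robur=86,83;petraea=169
gene	LOC115974879 (two-component response regulator ARR12-like)
locus	QP_miSeq36	Chr2	31588494	A	G	T	C	86
marker	QP_miSeq38
number	38
method	sanger
strand	+
fwd	GTAAATGGTAATTGAAAAGGCAT
rev	CCTGAAACTCTTGTTCAGAAGAT
expected_len	robur=193,petraea=193
fragments	robur=193;petraea=193
gene	LOC115974869 (transcription initiation factor TFIID subunit 5)
locus	QP_miSeq38_SNP1	scaffold492	52257	G	A	G	A	90
locus	QP_miSeq38_SNP2	scaffold492	52287	A	C	A	C	120
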