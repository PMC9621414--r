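snp	gene	effect_allele	weight
1:92077409	CDC7/TGFBR3	A	0.0002
3:99131755	COL8A1	A	0.0337
9:22031005	CDKN2BAS	A	0.3245
10:69998055	ATOH7	C	0.0852
10:96036306	PLCE1	A	0.0207
12:48044011	RPAP3	A	0.0523
12:83922912	TMTC2	G	0.1488
14:60789176	SIX1/6	T	0.1462
16:51482321	SALL1	G	0.0544
20:6578556	BMP2	C	0.2726
22:29100711	CHEK2	C	0.0702
1:8495945	RERE	C	0.0966
22:38175477	CARD10	G	0.0537
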