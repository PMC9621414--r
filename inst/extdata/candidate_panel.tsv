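rsid	chr_pos	gene	discovery_risk_allele	local_risk_allele	imputation_r2	discovery_effect_size
rs4658101	1:92077409	CDC7/TGFBR3	A	A	0.90	NA
rs2623325	3:99131755	COL8A1	A	A	0.90	NA
rs17658229	5:172191052	DUSP1	T	C	0.90	NA
rs17756712	6:625071	EXOC2	G	A	0.90	NA
rs7865618	9:22031005	CDKN2BAS	A	A	0.90	NA
rs1900005	10:69998055	ATOH7	C	C	0.90	NA
rs7072574	10:96036306	PLCE1	A	A	0.90	NA
rs1346	11:65337251	SSSCA1	A	A	0.56	NA
rs4936099	11:130280725	ADAMTS8	A	C	0.90	NA
rs11168187	12:48044011	RPAP3	A	A	0.90	NA
rs10862688	12:83922912	TMTC2	G	G	0.90	NA
rs4901977	14:60789176	SIX1/6	T	T	0.90	NA
rs1345467	16:51482321	SALL1	G	G	0.90	NA
rs6054374	20:6578556	BMP2	C	C	0.90	NA
rs1547014	22:29100711	CHEK2	C	C	0.90	NA
rs301801	1:8495945	RERE	C	C	0.90	NA
rs868153	6:122389955	HSF2	T	G	0.90	NA
rs5756813	22:38175477	CARD10	G	G	0.90	NA
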