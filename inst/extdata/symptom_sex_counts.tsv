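symptom	f_pos	f_neg	m_pos	m_neg
DEP	2116	816	1639	1120
IRR	1675	1252	1757	1005
PSY	301	2562	299	2396
VAB	802	2107	965	1794
APT	1581	1344	1484	1291
POB	1076	1833	1048	1713
COG	1726	1235	1583	1214
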