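label	rve_score
SYNREF01	3
SYNREF02	4
SYNREF03	5
SYNREF04	5
SYNREF05	6
SYNREF06	6
SYNREF07	7
SYNREF08	7
SYNREF09	7
SYNREF10	8
SYNREF11	8
SYNREF12	8
SYNREF13	9
SYNREF14	9
SYNREF15	9
SYNREF16	10
SYNREF17	10
SYNREF18	10
SYNREF19	11
SYNREF20	11
SYNREF21	11
SYNREF22	12
SYNREF23	12
SYNREF24	12
SYNREF25	13
SYNREF26	13
SYNREF27	13
SYNREF28	14
SYNREF29	14
SYNREF30	15
SYNREF31	15
SYNREF32	16
SYNREF33	16
SYNREF34	17
SYNREF35	17
SYNREF36	18
SYNREF37	18
SYNREF38	19
SYNREF39	20
SYNREF40	21
SYNREF41	22
SYNREF42	23
SYNREF43	24
SYNREF44	25
SYNREF45	27
SYNREF46	30
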