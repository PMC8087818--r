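rex_id	label	start	end	length_bp	symmetric	state	annotation
rex01	Ex1-2	123779335	123779396	61	No	Stable	Known
rex02	Ex2	123781451	123781529	78	Yes	Stable	Known
rex03	Ex2-3	123792608	123792668	60	Yes	Rare	Known
rex04	Ex2-3	123794962	123795075	113	No	Rare	Novel
rex05	Ex3	123809952	123810065	113	No	Stable	Known
rex06	Ex3-4	123822912	123823005	93	Yes	Rare	Novel
rex07	Ex3-4	123838491	123839151	660	Yes	Rare	Partially known
rex08	Ex4	123842161	123847474	5313	Yes	Variable	Known
rex09	Ex5	123847992	123848106	114	Yes	Variable	Known
rex10	Ex6	123892123	123892249	126	Yes	Variable	Known
rex11	Ex7	123903086	123903221	135	Yes	Variable	Known
rex12	Ex-8	123943555	123943720	165	Yes	Rare	Novel
rex13	Ex8	123954554	123954691	137	No	Stable	Known
rex14	Ex8-9	123962081	123962141	60	Yes	Rare	Partially known
rex15	Ex8-9	123969388	123969484	96	Yes	Rare	Known
rex16	Ex9	123969911	123971223	1312	No	Stable	Known
rex17	Ex9-10	123972856	123972892	36	Yes	Rare	Known
rex18	Ex10	123974905	123974966	61	No	Stable	Known
rex19	Ex11	123976141	123976343	202	No	Stable	Known
rex20	Ex12	123984240	123984302	62	No	Stable	Known
rex21	Ex13	123985880	123985996	116	No	Stable	Known
rex22	Ex14	123987351	123987523	172	No	Stable	Known
rex23	Ex15	123988860	123989001	141	Yes	Rare	Known
rex24	Ex17	123996909	123997053	144	Yes	Stable	Known
rex25	Ex18	123997475	123997552	77	No	Stable	Known
rex26	Ex19	124001472	124001516	44	No	Stable	Known
rex27	Ex20	124008157	124008318	161	No	Stable	Known
rex28	Ex21	124008564	124008671	107	No	Stable	Known
rex29	Ex22	124009058	124009089	31	No	Stable	Known
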