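parent	pattern	length_change	change_symmetric
rex07	L0:R-465	-465	Yes
rex08	L-4412:R0	-4412	No
rex08	L-4463:R0	-4463	No
rex08	L0:R-2445	-2445	Yes
rex08	L0:R-2656	-2656	No
rex08	L0:R-4536	-4536	Yes
rex08	L0:R-5231	-5231	No
rex09	L0:R-19	-19	No
rex11	L-11:R0	-11	No
rex11	L-47:R0	-47	No
rex16	L0:R12	12	Yes
rex17	L0:R4	4	No
rex18	L-12:R0	-12	Yes
rex19	L-13:R0	-13	No
rex19	L0:R93	93	Yes
rex21	L-3:R0	-3	Yes
rex23	L-4:R0	-4	No
rex23	L0:R4	4	No
rex24	L9:R0	9	Yes
rex25	L0:R26	26	No
rex26	L0:R4	4	No
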