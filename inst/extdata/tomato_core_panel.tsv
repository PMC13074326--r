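order	marker
1	T1M0546
2	T1M6565
3	T2M0112
4	T2M3180
5	T3M5319
6	T4M0210
7	T4M6000
8	T5M0701
9	T5M1237
10	T5M2207
11	T6M3024
12	T6M3582
13	T7M0019
14	T7M5397
15	T8M2758
16	T8M5194
17	T9M0714
18	T9M0982
19	TaM0641
20	TaM6451
21	TbM0724
22	TbM1162
23	TbM3021
24	TcM0679
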