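individual	DAB	DBB	DCB
1	3	2	5
2	3,4		5
3	1,3		
4	1		
5	3	2	5
6	3,4		8
7	1,4,7	9	
8	1,3,7	2	
9	1,3		
10	1,4	6	8
11	1,3,7		
12	1		
13	3,4	2,6	5
14	1,4		
15	1,4	6	
16	4	6	8
17	4	2,6	
18	3	2	5
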