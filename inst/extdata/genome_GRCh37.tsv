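chrom	length	centromere_start	centromere_end
1	249250621	121500000	128900000
2	243199373	90500000	96800000
3	198022430	87900000	93900000
4	191154276	48200000	52700000
5	180915260	46100000	50700000
6	171115067	58700000	63300000
7	159138663	58000000	61700000
8	146364022	43100000	48100000
9	141213431	47300000	50700000
10	135534747	38000000	42300000
11	135006516	51600000	55700000
12	133851895	34800000	38200000
13	115169878	16000000	19000000
14	107349540	16000000	19000000
15	102531392	17000000	20000000
16	90354753	35300000	38300000
17	81195210	22200000	25300000
18	78077248	15400000	19000000
19	59128983	24600000	28600000
20	63025520	26300000	29400000
21	48129895	11300000	14300000
22	51304566	13000000	16300000
X	155270560	58500000	61700000
Y	59373566	11600000	13400000
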