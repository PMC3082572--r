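lg	pattern_1	alleles_1	pattern_2	alleles_2
1	01011100011111000111	65	10100011100000111000	39
2	00101011011101001010	25	11010100100010110101	24
3	10110000000111110011	64	01001111111000001100	50
4	00000101011111101101	104	11111010100000010010	56
5	10000011000000000000	108	01111100111111111111	82
6	01001110111000110001	46	10110001000111001110	43
7	11111000010100101000	41	00000111101011010111	34
8	00110101001001010000	76	11001010110110101111	70
9	10001101011110011101	41	01110010100001100010	30
10	00011100111100011000	81	11100011000011100111	57
11	11000111111000111100	40	00111000000111000011	29
12	01110000110100011010	53	10001111001011100101	45
13	11010000100011111000	73	00101111011100000111	39
14	10101110110011101000	32	01010001001100010111	28
15	11011111001100011101	77	00100000110011100010	52
16	01101001010110000001	80	10010110101001111110	70
17	10110001100111001011	73	01001110011000110100	69
18	11110010111101011000	38	00001101000010100111	38
19	01100111111010010111	46	10011000000101101000	40
20	01110101111001100010	57	10001010000110011101	44
21	01100010011001100001	78	10011101100110011110	26
22	00010001000100111001	54	11101110111011000110	44
23	10101110010010111001	64	01010001101101000110	44
24	00010011111101100101	41	11101100000010011010	36
25	10111010100001010101	77	01000101011110101010	56
26	10111111010100101101	51	01000000101011010010	24
27	10011101011011101000	70	01100010100100010111	35
28	10001101110100001000	47	01110010001011110111	41
29	00111111010001001010	52	11000000101110110101	47
30	00011100000111111100	46	11100011111000000011	32
31	01101010010111000010	28	10010101101000111101	25
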