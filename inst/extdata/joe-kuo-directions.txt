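# Sobol' low-discrepancy sequence initialisation data: primitive polynomials
# (binary encoding, leading and constant term included) and initial direction
# numbers m_j for dimensions 2-32, from the published tables of Joe & Kuo
# (2008), 'Constructing Sobol sequences with better two-dimensional
# projections', SIAM J. Sci. Comput. 30(5). Dimension 1 is the van der
# Corput sequence in base 2 and needs no entry.
# columns: dim degree poly m1 m2 ...
2 1 3 1
3 2 7 1 3
4 3 11 1 3 1
5 3 13 1 1 1
6 4 19 1 1 3 3
7 4 25 1 3 5 13
8 5 37 1 1 5 5 17
9 5 41 1 1 5 5 5
10 5 47 1 1 7 11 19
11 5 55 1 1 5 1 1
12 5 59 1 1 1 3 11
13 5 61 1 3 5 5 31
14 6 67 1 3 3 9 7 49
15 6 91 1 1 1 15 21 21
16 6 97 1 3 1 13 27 49
17 6 103 1 1 1 15 7 5
18 6 109 1 3 1 15 13 25
19 6 115 1 1 5 5 19 61
20 7 131 1 3 7 11 23 15 103
21 7 137 1 3 7 13 13 15 69
22 7 143 1 1 3 13 7 35 63
23 7 145 1 3 5 9 1 25 53
24 7 157 1 3 1 13 9 35 107
25 7 167 1 3 1 5 27 61 31
26 7 171 1 1 5 11 19 41 61
27 7 185 1 3 5 3 3 13 69
28 7 191 1 1 7 13 1 19 1
29 7 193 1 3 7 5 13 19 59
30 7 203 1 1 3 9 25 29 41
31 7 211 1 3 5 13 23 1 55
32 7 213 1 3 7 3 13 59 17
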