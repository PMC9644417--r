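n_a,n_b,concordant,paired,expected
0,0,yes,absent,absent
1,0,yes,absent,equivocal
2,0,yes,absent,equivocal
5,0,yes,absent,equivocal
0,1,yes,absent,equivocal
1,1,yes,absent,equivocal
2,1,yes,absent,equivocal
5,1,yes,absent,equivocal
0,2,yes,absent,equivocal
1,2,yes,absent,equivocal
2,2,yes,absent,confirmed
5,2,yes,absent,confirmed
0,5,yes,absent,equivocal
1,5,yes,absent,equivocal
2,5,yes,absent,confirmed
5,5,yes,absent,confirmed
0,0,no,absent,absent
1,0,no,absent,equivocal
2,0,no,absent,equivocal
5,0,no,absent,equivocal
0,1,no,absent,equivocal
1,1,no,absent,equivocal
2,1,no,absent,equivocal
5,1,no,absent,equivocal
0,2,no,absent,equivocal
1,2,no,absent,equivocal
2,2,no,absent,equivocal
5,2,no,absent,equivocal
0,5,no,absent,equivocal
1,5,no,absent,equivocal
2,5,no,absent,equivocal
5,5,no,absent,equivocal
0,0,yes,4,absent
1,0,yes,4,equivocal
2,0,yes,4,equivocal
5,0,yes,4,equivocal
0,1,yes,4,equivocal
1,1,yes,4,equivocal
2,1,yes,4,equivocal
5,1,yes,4,equivocal
0,2,yes,4,equivocal
1,2,yes,4,equivocal
2,2,yes,4,confirmed
5,2,yes,4,confirmed
0,5,yes,4,equivocal
1,5,yes,4,equivocal
2,5,yes,4,confirmed
5,5,yes,4,confirmed
0,0,no,4,absent
1,0,no,4,equivocal
2,0,no,4,equivocal
5,0,no,4,equivocal
0,1,no,4,equivocal
1,1,no,4,equivocal
2,1,no,4,equivocal
5,1,no,4,equivocal
0,2,no,4,equivocal
1,2,no,4,equivocal
2,2,no,4,equivocal
5,2,no,4,equivocal
0,5,no,4,equivocal
1,5,no,4,equivocal
2,5,no,4,equivocal
5,5,no,4,equivocal
0,0,yes,5,absent
1,0,yes,5,equivocal
2,0,yes,5,equivocal
5,0,yes,5,equivocal
0,1,yes,5,equivocal
1,1,yes,5,confirmed
2,1,yes,5,confirmed
5,1,yes,5,confirmed
0,2,yes,5,equivocal
1,2,yes,5,confirmed
2,2,yes,5,confirmed
5,2,yes,5,confirmed
0,5,yes,5,equivocal
1,5,yes,5,confirmed
2,5,yes,5,confirmed
5,5,yes,5,confirmed
0,0,no,5,absent
1,0,no,5,equivocal
2,0,no,5,equivocal
5,0,no,5,equivocal
0,1,no,5,equivocal
1,1,no,5,equivocal
2,1,no,5,equivocal
5,1,no,5,equivocal
0,2,no,5,equivocal
1,2,no,5,equivocal
2,2,no,5,equivocal
5,2,no,5,equivocal
0,5,no,5,equivocal
1,5,no,5,equivocal
2,5,no,5,equivocal
5,5,no,5,equivocal
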