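"1","2","3","4","5","6","7","8","9a","9b","9c","9d","9e","9f","9g","9h","9i","10a","10b"
2,10,10,4,3,1,1,4,3,3,3,0,1,2,1,3,3,6,3
1,1,6,4,2,1,1,0,1,1,1,0,1,1,1,1,0,3,0
1,1,8,2,3,1,2,3,1,4,1,2,0,2,3,3,3,6,3
3,3,4,1,2,1,1,2,1,2,,3,4,4,1,2,4,3,0
0,2,0,3,0,0,0,1,2,2,3,1,1,0,1,2,0,7,4
0,1,1,2,0,0,0,0,0,1,1,0,0,0,0,0,0,3,0
0,1,1,2,0,0,0,0,3,2,2,4,3,1,2,2,3,3,0
4,2,0,2,1,0,1,1,3,1,3,1,3,3,0,0,0,10,7
2,8,8,1,2,0,1,2,1,2,0,3,0,3,3,2,1,8,5
2,7,5,0,1,1,1,1,0,1,0,0,4,1,2,1,0,3,0
0,5,3,4,3,1,0,2,0,4,4,3,1,0,2,2,3,7,4
1,8,9,3,1,0,1,2,2,1,1,0,1,1,0,0,3,4,1
4,6,9,1,3,1,2,4,1,2,3,2,4,2,2,2,1,10,9
3,1,4,4,1,0,1,3,3,1,4,2,1,1,2,3,0,10,9
0,3,1,0,0,0,0,0,0,0,0,0,1,1,0,1,0,4,1
0,8,5,3,4,0,3,1,2,4,2,4,4,4,3,3,2,10,9
3,6,5,3,3,0,3,3,1,2,,3,2,4,3,2,1,10,10
1,3,4,1,2,0,4,4,1,2,1,0,4,1,3,3,3,8,5
2,4,2,1,0,1,0,0,3,1,1,0,1,0,0,1,2,7,4
4,9,9,1,4,1,4,4,3,0,4,3,3,3,4,2,2,10,7
3,5,6,3,1,1,3,1,0,0,1,3,0,3,0,3,1,4,1
3,5,6,2,4,0,2,4,1,4,2,2,2,3,2,3,1,10,8
0,1,2,1,0,0,0,0,0,1,0,0,1,0,1,0,0,3,0
4,8,5,4,2,1,1,2,1,2,3,3,0,1,2,4,3,10,9
3,6,8,3,2,1,2,3,3,3,3,1,1,1,3,3,1,7,4
4,5,7,3,4,1,4,4,4,4,3,3,3,4,3,3,4,10,8
4,10,10,4,3,1,2,4,4,2,4,4,2,1,4,4,4,10,10
1,7,7,2,2,1,0,1,2,2,2,1,1,3,2,3,4,10,7
4,6,8,3,4,1,2,2,3,4,3,3,3,1,3,3,3,7,4
4,8,4,4,4,0,4,4,4,4,4,3,4,4,4,3,4,10,8
0,,4,2,2,0,0,1,0,1,0,0,3,1,1,1,1,4,1
3,10,8,4,3,0,3,3,3,2,3,3,2,3,3,1,1,10,8
0,1,7,2,3,1,0,2,4,0,3,0,1,4,2,2,1,5,2
2,8,7,2,4,1,1,3,2,2,0,2,2,2,3,4,3,10,10
0,6,9,4,3,0,1,1,4,3,2,2,3,2,3,3,3,3,0
4,8,10,2,3,1,2,1,1,3,2,4,2,3,4,4,4,6,3
2,6,7,0,2,0,3,3,3,3,2,2,3,4,4,4,4,7,4
0,1,3,2,1,1,3,2,1,2,2,2,2,4,1,0,0,6,3
3,9,7,2,3,1,3,3,1,4,3,4,1,2,3,2,3,5,2
2,1,9,0,2,0,1,2,1,0,4,4,1,3,1,1,0,10,7
2,7,5,0,1,1,3,2,4,1,1,3,3,0,1,1,0,6,3
3,7,8,3,3,0,2,2,1,3,0,3,2,3,4,4,3,6,3
2,0,1,0,1,1,1,1,0,1,0,2,0,1,1,0,1,3,0
1,7,9,3,2,0,1,1,3,0,1,1,2,4,2,2,3,5,2
1,1,3,0,4,0,3,3,0,1,0,2,1,0,2,1,1,9,6
4,4,9,4,4,0,4,4,4,4,4,3,3,4,4,4,4,9,6
2,10,5,2,1,1,2,2,3,1,1,3,3,4,4,3,1,8,5
4,6,1,2,3,0,4,2,1,1,2,1,0,2,2,1,0,5,2
2,6,9,2,2,0,0,2,3,2,2,3,3,4,4,4,4,8,5
2,2,9,4,1,0,1,3,4,4,1,3,4,4,3,3,2,8,5
1,2,1,1,0,0,0,1,1,2,1,2,3,0,0,1,1,7,4
0,1,0,0,1,0,1,0,4,2,1,3,1,2,1,1,0,5,2
3,5,3,3,2,0,1,0,1,2,1,0,4,1,3,2,3,8,5
2,7,3,2,3,0,4,4,2,3,4,1,4,2,4,4,3,5,2
0,4,1,2,0,0,1,1,0,4,1,1,1,0,1,1,0,6,3
1,4,6,4,1,1,2,3,0,4,2,1,1,1,3,3,2,7,4
1,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,9,6
1,5,5,4,2,1,4,3,1,0,2,1,1,4,0,0,1,4,1
3,9,6,2,2,1,3,3,1,2,2,2,3,1,2,1,2,10,10
0,2,1,1,0,0,1,0,4,2,4,0,4,1,1,0,0,4,1
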