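Demo_key,Year,Age,Gender,Weight,Country,Drug,PT
1,y3,a2,g1,w2,c3,d1,s1
1,y3,a2,g1,w2,c3,d2,s1
1,y3,a2,g1,w2,c3,d3,s1
2,y1,a1,g2,w2,c1,d2,s2
2,y1,a1,g2,w2,c1,d3,s2
3,y2,a2,g2,w2,c2,d1,s1
3,y2,a2,g2,w2,c2,d3,s1
3,y2,a2,g2,w2,c2,d1,s2
3,y2,a2,g2,w2,c2,d3,s2
4,y1,a2,g1,w1,c3,d1,s1
4,y1,a2,g1,w1,c3,d3,s1
5,y1,a1,g2,w1,c2,d2,s1
6,y3,a2,g1,w2,c1,d2,s3
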