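sample_id,appearance,viscosity_cp
1,transparent,153
2,transparent,179
3,transparent,272
4,transparent,547
5,transparent,620
6,transparent,756
7,transparent,1040
8,transparent,1130
9,transparent,1290
10,transparent,1560
11,transparent,1930
12,transparent,2580
13,transparent,3520
14,transparent,5520
15,transparent,7060
16,transparent,9480
17,transparent,12950
18,transparent,15530
19,transparent,18930
20,transparent,22780
21,transparent,31160
1,opaque,152
2,opaque,202
3,opaque,306
4,opaque,544
5,opaque,687
6,opaque,827
7,opaque,1110
8,opaque,1230
9,opaque,1420
10,opaque,1710
11,opaque,2140
12,opaque,2980
13,opaque,4050
14,opaque,5870
15,opaque,7420
16,opaque,10630
17,opaque,14140
18,opaque,16850
19,opaque,20440
20,opaque,25650
21,opaque,33810
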