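point_id;row;col;x_deg;y_deg;quadrant;sensitivity_db;Retina_um;GCL_um
0;1;1;-14,3601;9,2564;superior-nasal;0;250,126;15,547
1;1;2;-10,6381;9,7134;superior-nasal;0;252,462;21,493
2;1;3;-6,916;10,1705;superior-nasal;12;259,996;30,28
3;1;4;-3,194;10,6275;superior-nasal;12;236,904;23,11
4;1;5;0,5281;11,0845;superior-temporal;13;252,189;19,437
5;1;6;4,2501;11,5415;superior-temporal;13;248,994;18,441
6;1;7;7,9722;11,9985;superior-temporal;12;248,818;26,938
7;1;8;11,6942;12,4555;superior-temporal;18;253,007;17,065
8;2;1;-13,9793;6,1547;superior-nasal;10;259,183;15,559
9;2;2;-10,2572;6,6117;superior-nasal;10;251,726;19,002
10;2;3;-6,5352;7,0688;superior-nasal;15;253,8;10,856
11;2;4;-2,8131;7,5258;superior-nasal;14;249,458;19,494
12;2;5;0,9089;7,9828;superior-temporal;16;261,118;18,043
13;2;6;4,631;8,4398;superior-temporal;13;258,571;11,267
14;2;7;8,353;8,8968;superior-temporal;14;247,361;23,972
15;2;8;12,0751;9,3538;superior-temporal;16;250,529;12,6
16;3;1;-13,5984;3,053;superior-nasal;13;254,175;15,544
17;3;2;-9,8764;3,51;superior-nasal;19;255,494;18,967
18;3;3;-6,1543;3,967;superior-nasal;11;254,611;16,471
19;3;4;-2,4323;4,4241;superior-nasal;6;255,75;15,559
20;3;5;1,2898;4,8811;superior-temporal;17;249,705;21,552
21;3;6;5,0118;5,3381;superior-temporal;15;247,942;17,203
22;3;7;8,7339;5,7951;superior-temporal;15;259,538;18,433
23;3;8;12,4559;6,2521;superior-temporal;13;259,129;10,195
24;4;1;-13,2176;-0,0487;superior-nasal;3;243,866;18,968
25;4;2;-9,4955;0,4083;superior-nasal;15;248,327;20,484
26;4;3;-5,7735;0,8653;superior-nasal;12;241,809;10,548
27;4;4;-2,0514;1,3223;superior-nasal;5;250,812;15,803
28;4;5;1,6706;1,7794;superior-temporal;11;246,755;20,714
29;4;6;5,3927;2,2364;superior-temporal;14;247,776;29,949
30;4;7;9,1147;2,6934;superior-temporal;15;247,164;21,134
31;4;8;12,8367;3,1504;superior-temporal;0;250,943;18,829
32;5;1;-12,8367;-3,1504;inferior-nasal;0;249,665;12,106
33;5;2;-9,1147;-2,6934;inferior-nasal;10;252,342;15,538
34;5;3;-5,3927;-2,2364;inferior-nasal;5;235,895;11,544
35;5;4;-1,6706;-1,7794;inferior-nasal;0;250,482;0
36;5;5;2,0514;-1,3223;inferior-temporal;11;252,216;21,158
37;5;6;5,7735;-0,8653;inferior-temporal;16;248,661;11,733
38;5;7;9,4955;-0,4083;inferior-temporal;16;251,206;23,995
39;5;8;13,2176;0,0487;inferior-temporal;15;256,591;19,166
40;6;1;-12,4559;-6,2521;inferior-nasal;4;247,497;17,076
41;6;2;-8,7339;-5,7951;inferior-nasal;0;250,876;19,843
42;6;3;-5,0118;-5,3381;inferior-nasal;9;251,244;12,967
43;6;4;-1,2898;-4,8811;inferior-nasal;2;253,569;5,993
44;6;5;2,4323;-4,4241;inferior-temporal;14;248,843;16,616
45;6;6;6,1543;-3,967;inferior-temporal;18;257,22;15,124
46;6;7;9,8764;-3,51;inferior-temporal;14;250,18;23,642
47;6;8;13,5984;-3,053;inferior-temporal;13;252,041;17,101
48;7;1;-12,0751;-9,3538;inferior-nasal;5;250,11;9,636
49;7;2;-8,353;-8,8968;inferior-nasal;1;248,563;12,436
50;7;3;-4,631;-8,4398;inferior-nasal;16;245,429;21,112
51;7;4;-0,9089;-7,9828;inferior-nasal;3;247,127;16,021
52;7;5;2,8131;-7,5258;inferior-temporal;13;250,349;11,679
53;7;6;6,5352;-7,0688;inferior-temporal;15;252,092;21,211
54;7;7;10,2572;-6,6117;inferior-temporal;13;253,725;27,031
55;7;8;13,9793;-6,1547;inferior-temporal;14;253,46;16,186
56;8;1;-11,6942;-12,4555;inferior-nasal;0;248,505;0
57;8;2;-7,9722;-11,9985;inferior-nasal;3;255,445;16,898
58;8;3;-4,2501;-11,5415;inferior-nasal;12;248,094;8,62
59;8;4;-0,5281;-11,0845;inferior-nasal;2;239,831;17,386
60;8;5;3,194;-10,6275;inferior-temporal;10;249,534;21,801
61;8;6;6,916;-10,1705;inferior-temporal;0;251,195;19,35
62;8;7;10,6381;-9,7134;inferior-temporal;11;249,331;8,356
63;8;8;14,3601;-9,2564;inferior-temporal;13;238,442;14,801
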