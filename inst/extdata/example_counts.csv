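"nucleus_id","channel","count","diameter_um"
1,"myc",4,8.1
2,"myc",2,8.8
3,"myc",3,8.7
4,"myc",3,9.7
5,"myc",2,8.7
6,"myc",3,9.2
7,"myc",2,9.2
8,"myc",2,8.7
9,"myc",4,8.7
10,"myc",1,9.3
11,"myc",5,8.5
12,"myc",5,9
13,"myc",3,9.3
14,"myc",2,10.2
15,"myc",2,8.3
16,"myc",4,9.1
17,"myc",1,9.2
18,"myc",4,9.4
19,"myc",1,9.4
20,"myc",1,10.2
21,"myc",0,8.7
22,"myc",1,8.5
23,"myc",3,8.6
24,"myc",4,8.4
25,"myc",4,8.6
26,"myc",1,8.1
27,"myc",3,9.5
28,"myc",4,8.9
29,"myc",0,9.6
30,"myc",0,9
31,"myc",2,10
32,"myc",1,9.5
33,"myc",1,9.3
34,"myc",6,9.1
35,"myc",3,10
36,"myc",3,8.9
37,"myc",0,7.8
38,"myc",6,9.4
39,"myc",0,9.3
40,"myc",3,7.7
41,"myc",4,9.7
42,"myc",5,8.3
43,"myc",3,9.2
44,"myc",2,9
45,"myc",4,9.1
46,"myc",2,8.8
47,"myc",2,9.9
48,"myc",1,9.4
49,"myc",3,8.4
50,"myc",3,9
51,"myc",0,8.3
52,"myc",3,9.6
53,"myc",2,9.5
54,"myc",2,7.9
55,"myc",3,9.1
56,"myc",3,9.7
57,"myc",0,8.9
58,"myc",1,8.8
59,"myc",2,8.8
60,"myc",1,9.5
1,"terc",0,8.8
2,"terc",3,8.8
3,"terc",1,8.2
4,"terc",2,8.9
5,"terc",0,8.6
6,"terc",5,9
7,"terc",2,8.4
8,"terc",2,8.3
9,"terc",2,8.7
10,"terc",0,9.3
11,"terc",0,8.4
12,"terc",0,9.1
13,"terc",0,8.6
14,"terc",0,9
15,"terc",0,10
16,"terc",0,8.5
17,"terc",1,8.3
18,"terc",1,9.3
19,"terc",3,9.2
20,"terc",3,8.8
21,"terc",4,9.3
22,"terc",0,8.3
23,"terc",2,8.5
24,"terc",0,10
25,"terc",2,9.5
26,"terc",0,9.4
27,"terc",1,10
28,"terc",1,9.1
29,"terc",0,9.5
30,"terc",2,9.6
31,"terc",1,8.3
32,"terc",3,9
33,"terc",1,10.4
34,"terc",1,9.7
35,"terc",3,8.5
36,"terc",1,7.2
37,"terc",0,9.2
38,"terc",2,8.8
39,"terc",0,8.6
40,"terc",0,9.2
41,"terc",0,10
42,"terc",1,9
43,"terc",2,9
44,"terc",1,9.9
45,"terc",0,8.8
46,"terc",2,8.6
47,"terc",1,9.1
48,"terc",3,8
49,"terc",0,9.7
50,"terc",1,10.3
51,"terc",0,8.8
52,"terc",0,9.6
53,"terc",4,8.7
54,"terc",0,9.1
55,"terc",2,9.2
56,"terc",3,9.7
57,"terc",1,9.7
58,"terc",0,9.1
59,"terc",2,9.4
60,"terc",3,8.8
1,"se7",1,8.6
2,"se7",0,9.3
3,"se7",1,8.7
4,"se7",1,7.4
5,"se7",1,9.4
6,"se7",2,9.2
7,"se7",0,9.4
8,"se7",1,9.3
9,"se7",0,8.6
10,"se7",1,9.6
11,"se7",1,8.6
12,"se7",2,9.9
13,"se7",2,9.1
14,"se7",0,9
15,"se7",0,9
16,"se7",1,9.1
17,"se7",0,8.9
18,"se7",0,9.3
19,"se7",1,8.8
20,"se7",0,9.4
21,"se7",0,9.8
22,"se7",0,9.4
23,"se7",0,8.9
24,"se7",1,8.8
25,"se7",1,9
26,"se7",0,9.1
27,"se7",2,9
28,"se7",1,8.7
29,"se7",2,9
30,"se7",0,8.4
31,"se7",1,9.1
32,"se7",0,9.7
33,"se7",2,9.8
34,"se7",0,9.7
35,"se7",1,8.5
36,"se7",2,10.1
37,"se7",3,8.7
38,"se7",2,9.2
39,"se7",0,8.3
40,"se7",1,9.1
41,"se7",1,10
42,"se7",2,9.1
43,"se7",1,9.6
44,"se7",3,8.8
45,"se7",0,9.2
46,"se7",0,8.1
47,"se7",1,9.1
48,"se7",1,8.9
49,"se7",2,9.3
50,"se7",1,8.3
51,"se7",0,8.9
52,"se7",0,8.8
53,"se7",0,9.3
54,"se7",1,8.5
55,"se7",1,7.5
56,"se7",2,9.4
57,"se7",2,8.7
58,"se7",0,9.4
59,"se7",1,9.3
60,"se7",0,9.6
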