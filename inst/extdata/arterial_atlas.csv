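# Default arterial atlas: 74 named intracranial branches grouped into 19 territory chunks.
# Editable; columns: branch_id, branch_name, chunk_id, chunk_name.
"branch_id","branch_name","chunk_id","chunk_name"
1,"BA proximal",1,"BA"
2,"BA mid",1,"BA"
3,"BA distal",1,"BA"
4,"BA pontine branches",1,"BA"
5,"Lt cavernous ICA",2,"Lt ICA"
6,"Lt supraclinoid ICA",2,"Lt ICA"
7,"Lt ophthalmic A",2,"Lt ICA"
8,"Lt PComA",2,"Lt ICA"
9,"Lt anterior choroidal A",2,"Lt ICA"
10,"Rt cavernous ICA",3,"Rt ICA"
11,"Rt supraclinoid ICA",3,"Rt ICA"
12,"Rt ophthalmic A",3,"Rt ICA"
13,"Rt PComA",3,"Rt ICA"
14,"Rt anterior choroidal A",3,"Rt ICA"
15,"Lt VA V4 proximal",4,"Lt VA"
16,"Lt VA V4 distal",4,"Lt VA"
17,"Rt VA V4 proximal",5,"Rt VA"
18,"Rt VA V4 distal",5,"Rt VA"
19,"Lt ACA A1",6,"Lt basal ACA"
20,"Lt ACA A2",6,"Lt basal ACA"
21,"Rt ACA A1",7,"Rt basal ACA"
22,"Rt ACA A2",7,"Rt basal ACA"
23,"Lt MCA M1",8,"Lt basal MCA"
24,"Lt MCA M2 superior",8,"Lt basal MCA"
25,"Lt MCA M2 inferior",8,"Lt basal MCA"
26,"Rt MCA M1",9,"Rt basal MCA"
27,"Rt MCA M2 superior",9,"Rt basal MCA"
28,"Rt MCA M2 inferior",9,"Rt basal MCA"
29,"Lt PCA P1",10,"Lt basal PCA"
30,"Lt PCA P2",10,"Lt basal PCA"
31,"Rt PCA P1",11,"Rt basal PCA"
32,"Rt PCA P2",11,"Rt basal PCA"
33,"Lt pericallosal A",12,"Lt pial ACA"
34,"Lt callosomarginal A",12,"Lt pial ACA"
35,"Lt frontopolar A",12,"Lt pial ACA"
36,"Lt orbitofrontal A",12,"Lt pial ACA"
37,"Lt paracentral A",12,"Lt pial ACA"
38,"Rt pericallosal A",13,"Rt pial ACA"
39,"Rt callosomarginal A",13,"Rt pial ACA"
40,"Rt frontopolar A",13,"Rt pial ACA"
41,"Rt orbitofrontal A",13,"Rt pial ACA"
42,"Rt paracentral A",13,"Rt pial ACA"
43,"Lt prefrontal A",14,"Lt pial MCA"
44,"Lt precentral A",14,"Lt pial MCA"
45,"Lt central A",14,"Lt pial MCA"
46,"Lt anterior parietal A",14,"Lt pial MCA"
47,"Lt posterior parietal A",14,"Lt pial MCA"
48,"Lt angular A",14,"Lt pial MCA"
49,"Lt anterior temporal A",14,"Lt pial MCA"
50,"Lt posterior temporal A",14,"Lt pial MCA"
51,"Rt prefrontal A",15,"Rt pial MCA"
52,"Rt precentral A",15,"Rt pial MCA"
53,"Rt central A",15,"Rt pial MCA"
54,"Rt anterior parietal A",15,"Rt pial MCA"
55,"Rt posterior parietal A",15,"Rt pial MCA"
56,"Rt angular A",15,"Rt pial MCA"
57,"Rt anterior temporal A",15,"Rt pial MCA"
58,"Rt posterior temporal A",15,"Rt pial MCA"
59,"Lt parieto-occipital A",16,"Lt pial PCA"
60,"Lt calcarine A",16,"Lt pial PCA"
61,"Lt PCA posterior temporal A",16,"Lt pial PCA"
62,"Lt splenial A",16,"Lt pial PCA"
63,"Rt parieto-occipital A",17,"Rt pial PCA"
64,"Rt calcarine A",17,"Rt pial PCA"
65,"Rt PCA posterior temporal A",17,"Rt pial PCA"
66,"Rt splenial A",17,"Rt pial PCA"
67,"Lt PICA",18,"Lt cbll"
68,"Lt AICA",18,"Lt cbll"
69,"Lt SCA",18,"Lt cbll"
70,"Lt vermian A",18,"Lt cbll"
71,"Rt PICA",19,"Rt cbll"
72,"Rt AICA",19,"Rt cbll"
73,"Rt SCA",19,"Rt cbll"
74,"Rt vermian A",19,"Rt cbll"
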