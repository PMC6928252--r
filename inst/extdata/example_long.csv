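"condition","time","time_unit","variable","block","replicate_id","pairing_id","value"
"c1",0,"day","x01","X","X_a1","p1",-0.435551325215784
"c1",0,"day","x02","X","X_a1","p1",0.119388743467097
"c1",0,"day","x03","X","X_a1","p1",0.103189376246425
"c1",0,"day","x01","X","X_a2","p2",-0.225717589288764
"c1",0,"day","x02","X","X_a2","p2",0.44939976001231
"c1",0,"day","x03","X","X_a2","p2",0.196470722643022
"c1",1,"day","x01","X","X_a1","p1",-1.48648023260703
"c1",1,"day","x02","X","X_a1","p1",-0.119948724980294
"c1",1,"day","x03","X","X_a1","p1",-0.496213874875507
"c1",1,"day","x01","X","X_a2","p2",-1.58575936872749
"c1",1,"day","x02","X","X_a2","p2",-0.250063809587433
"c1",1,"day","x03","X","X_a2","p2",-0.844358287015466
"c1",2,"day","x01","X","X_a1","p1",-1.13082148938067
"c1",2,"day","x02","X","X_a1","p1",0.0815557956363654
"c1",2,"day","x03","X","X_a1","p1",-0.245045301614677
"c1",2,"day","x01","X","X_a2","p2",-0.544777826450171
"c1",2,"day","x02","X","X_a2","p2",0.725995460042019
"c1",2,"day","x03","X","X_a2","p2",0.375585508987987
"c2",0,"day","x01","X","X_a1","p1",0.108483569999457
"c2",0,"day","x02","X","X_a1","p1",-0.26681050578609
"c2",0,"day","x03","X","X_a1","p1",-0.0507714018113813
"c2",0,"day","x01","X","X_a2","p2",-0.125495358794538
"c2",0,"day","x02","X","X_a2","p2",-0.377078957136768
"c2",0,"day","x03","X","X_a2","p2",-0.40261172361735
"c2",1,"day","x01","X","X_a1","p1",0.344383490341526
"c2",1,"day","x02","X","X_a1","p1",-0.354028500134734
"c2",1,"day","x03","X","X_a1","p1",-0.0564438864680421
"c2",1,"day","x01","X","X_a2","p2",0.317239548765122
"c2",1,"day","x02","X","X_a2","p2",-0.322922121719218
"c2",1,"day","x03","X","X_a2","p2",-0.165006361044707
"c2",2,"day","x01","X","X_a1","p1",0.435406851355213
"c2",2,"day","x02","X","X_a1","p1",-0.228528670248881
"c2",2,"day","x03","X","X_a1","p1",-0.0248116060590474
"c2",2,"day","x01","X","X_a2","p2",0.501743509871289
"c2",2,"day","x02","X","X_a2","p2",-0.144293955468467
"c2",2,"day","x03","X","X_a2","p2",0.121408035223034
"c3",0,"day","x01","X","X_a1","p1",0.291931085119249
"c3",0,"day","x02","X","X_a1","p1",0.151530954604917
"c3",0,"day","x03","X","X_a1","p1",0.297366285922895
"c3",0,"day","x01","X","X_a2","p2",0.116385213890504
"c3",0,"day","x02","X","X_a2","p2",0.0121326614529691
"c3",0,"day","x03","X","X_a2","p2",-0.0140456595732764
"c3",1,"day","x01","X","X_a1","p1",0.469623928638962
"c3",1,"day","x02","X","X_a1","p1",0.0649865530734379
"c3",1,"day","x03","X","X_a1","p1",0.258025381337651
"c3",1,"day","x01","X","X_a2","p2",0.44524902696072
"c3",1,"day","x02","X","X_a2","p2",0.0630194677491806
"c3",1,"day","x03","X","X_a2","p2",0.199605000851303
"c3",2,"day","x01","X","X_a1","p1",-0.106992690146106
"c3",2,"day","x02","X","X_a1","p1",-0.471215216259227
"c3",2,"day","x03","X","X_a1","p1",-0.325220459253711
"c3",2,"day","x01","X","X_a2","p2",0.737498954222476
"c3",2,"day","x02","X","X_a2","p2",0.268326781361033
"c3",2,"day","x03","X","X_a2","p2",0.350514862721514
"c1",0,"day","y01","Y","Y_a1","p1",-0.835052848552795
"c1",0,"day","y02","Y","Y_a1","p1",-0.0172413293925135
"c1",0,"day","y01","Y","Y_a2","p2",-0.699846013411775
"c1",0,"day","y02","Y","Y_a2","p2",0.0528183737777644
"c1",1,"day","y01","Y","Y_a1","p1",-0.363348759199614
"c1",1,"day","y02","Y","Y_a1","p1",-0.305978297625433
"c1",1,"day","y01","Y","Y_a2","p2",-0.676852764301897
"c1",1,"day","y02","Y","Y_a2","p2",-0.571335998185031
"c1",2,"day","y01","Y","Y_a1","p1",-1.35482666187629
"c1",2,"day","y02","Y","Y_a1","p1",-0.236411764771885
"c1",2,"day","y01","Y","Y_a2","p2",-0.714667990032743
"c1",2,"day","y02","Y","Y_a2","p2",0.340369134651561
"c2",0,"day","y01","Y","Y_a1","p1",0.469411048371425
"c2",0,"day","y02","Y","Y_a1","p1",-0.0295221772544982
"c2",0,"day","y01","Y","Y_a2","p2",0.0888920014551794
"c2",0,"day","y02","Y","Y_a2","p2",-0.316185444534232
"c2",1,"day","y01","Y","Y_a1","p1",-0.167343475706587
"c2",1,"day","y02","Y","Y_a1","p1",-0.165855525381096
"c2",1,"day","y01","Y","Y_a2","p2",-0.154930626869478
"c2",1,"day","y02","Y","Y_a2","p2",-0.18986891623968
"c2",2,"day","y01","Y","Y_a1","p1",0.535678312286428
"c2",2,"day","y02","Y","Y_a1","p1",-0.117102104504957
"c2",2,"day","y01","Y","Y_a2","p2",0.581915262059149
"c2",2,"day","y02","Y","Y_a2","p2",0.0677536126684924
"c3",0,"day","y01","Y","Y_a1","p1",0.514736175489051
"c3",0,"day","y02","Y","Y_a1","p1",0.206685188454184
"c3",0,"day","y01","Y","Y_a2","p2",0.346969883844917
"c3",0,"day","y02","Y","Y_a2","p2",0.0189173303610618
"c3",1,"day","y01","Y","Y_a1","p1",0.142867245094089
"c3",1,"day","y02","Y","Y_a1","p1",0.164851034996222
"c3",1,"day","y01","Y","Y_a2","p2",0.267631790314129
"c3",1,"day","y02","Y","Y_a2","p2",0.198841902953594
"c3",2,"day","y01","Y","Y_a1","p1",-0.111319443427759
"c3",2,"day","y02","Y","Y_a1","p1",-0.423743587538561
"c3",2,"day","y01","Y","Y_a2","p2",0.799720132975452
"c3",2,"day","y02","Y","Y_a2","p2",0.352234094070043
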