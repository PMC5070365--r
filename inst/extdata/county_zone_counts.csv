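mode,group,band,n_districts,n_inhabitants
car,GP,<5,183,191662
car,GP,5 to <10,235,41486
car,GP,10 to <15,37,4918
car,GP,15 to <20,8,1032
car,GP,>=20,1,4
pt,GP,<1,53,163062
pt,GP,1 to <2,152,34284
pt,GP,2 to <3,119,26753
pt,GP,3 to <4,25,5085
pt,GP,4 to <5,6,911
pt,GP,>=5,1,34
pt,GP,NO_CONNECTION,109,8973
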