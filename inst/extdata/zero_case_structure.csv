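region,category,tracts_total,n0,n1,n2,n3
Valencia,MND,3473,3229,230,13,1
Valencia,ALS,3473,3264,199,10,0
Valencia,PMA,3473,3447,25,1,0
Valencia,PLS,3473,3463,10,0,0
Catalonia,MND,5018,4485,481,46,6
Catalonia,ALS,5018,4538,440,37,3
Catalonia,PMA,5018,5004,14,0,0
Catalonia,PLS,5018,5014,4,0,0
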