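region,measure,category,point,lower,upper
Valencia,prevalence,MND,4.216,2.652,6.334
Valencia,prevalence,ALS,3.249,1.911,5.120
Valencia,prevalence,PMA,0.480,0.065,1.650
Valencia,prevalence,PLS,0.378,0.046,1.896
Catalonia,prevalence,MND,5.627,3.990,7.662
Catalonia,prevalence,ALS,4.721,3.248,6.608
Catalonia,prevalence,PMA,0.602,0.008,0.634
Catalonia,prevalence,PLS,0.662,0.000,1.987
Valencia,incidence,MND,1.390,0.822,2.165
Valencia,incidence,ALS,1.080,0.598,1.754
Valencia,incidence,PMA,0.222,0.009,1.027
Valencia,incidence,PLS,0.202,1.306e-09,0.564
Catalonia,incidence,MND,2.346,1.682,3.152
Catalonia,incidence,ALS,1.935,1.351,2.656
Catalonia,incidence,PMA,0.415,0.225,0.628
Catalonia,incidence,PLS,0.476,0.409,0.544
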