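region,ALS,PMA,PLS
Valencia,219,27,10
Catalonia,524,14,4
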