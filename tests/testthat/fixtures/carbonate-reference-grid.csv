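ta,ph,temp,salinity,pco2,dic
2000.0,7.7,8.0,30.0,844.371710,1968.640366
2000.0,7.7,8.0,34.0,825.540389,1957.643639
2000.0,7.7,8.0,38.0,813.922984,1946.897297
2000.0,7.7,14.0,30.0,869.639946,1946.074592
2000.0,7.7,14.0,34.0,848.208466,1933.448665
2000.0,7.7,14.0,38.0,834.257453,1921.012005
2000.0,7.7,20.0,30.0,889.837444,1921.940781
2000.0,7.7,20.0,34.0,865.454328,1907.379488
2000.0,7.7,20.0,38.0,848.802663,1892.968527
2000.0,8.0,8.0,30.0,399.521008,1883.686965
2000.0,8.0,8.0,34.0,388.100504,1866.300657
2000.0,8.0,8.0,38.0,380.163768,1848.987604
2000.0,8.0,14.0,30.0,406.124628,1851.829646
2000.0,8.0,14.0,34.0,393.068048,1831.679992
2000.0,8.0,14.0,38.0,383.617524,1811.628139
2000.0,8.0,20.0,30.0,409.234265,1816.337438
2000.0,8.0,20.0,34.0,394.394968,1793.171229
2000.0,8.0,20.0,38.0,383.282386,1770.165491
2000.0,8.3,8.0,30.0,180.195325,1766.146873
2000.0,8.3,8.0,34.0,173.135768,1738.767759
2000.0,8.3,8.0,38.0,167.752569,1711.650120
2000.0,8.3,14.0,30.0,179.192559,1719.005503
2000.0,8.3,14.0,34.0,171.236220,1688.111076
2000.0,8.3,14.0,38.0,165.021346,1657.661352
2000.0,8.3,20.0,30.0,176.112541,1667.346808
2000.0,8.3,20.0,34.0,167.268834,1632.988459
2000.0,8.3,20.0,38.0,160.233893,1599.311806
2250.0,7.7,8.0,30.0,951.251308,2217.828594
2250.0,7.7,8.0,34.0,930.285226,2206.030110
2250.0,7.7,8.0,38.0,917.450461,2194.534198
2250.0,7.7,14.0,30.0,979.980943,2192.994956
2250.0,7.7,14.0,34.0,956.134367,2179.460344
2250.0,7.7,14.0,38.0,940.721402,2166.162378
2250.0,7.7,20.0,30.0,1003.053944,2166.474667
2250.0,7.7,20.0,34.0,975.935929,2150.870488
2250.0,7.7,20.0,38.0,957.536184,2135.462033
2250.0,8.0,8.0,30.0,450.654923,2124.776387
2250.0,8.0,8.0,34.0,437.992274,2106.220579
2250.0,8.0,8.0,38.0,429.260280,2087.776387
2250.0,8.0,14.0,30.0,458.324459,2089.848196
2250.0,8.0,14.0,34.0,443.851575,2068.329017
2250.0,8.0,14.0,38.0,433.447749,2046.950644
2250.0,8.0,20.0,30.0,462.090119,2050.931838
2250.0,8.0,20.0,34.0,445.642170,2026.173715
2250.0,8.0,20.0,38.0,433.399392,2001.627719
2250.0,8.3,8.0,30.0,203.693655,1996.460848
2250.0,8.3,8.0,34.0,195.888185,1967.265718
2250.0,8.3,8.0,38.0,189.974829,1938.393206
2250.0,8.3,14.0,30.0,202.721399,1944.719147
2250.0,8.3,14.0,34.0,193.920637,1911.742600
2250.0,8.3,14.0,38.0,187.084784,1879.291524
2250.0,8.3,20.0,30.0,199.417989,1887.991310
2250.0,8.3,20.0,34.0,189.629751,1851.290459
2250.0,8.3,20.0,38.0,181.881314,1815.377053
2500.0,7.7,8.0,30.0,1058.130906,2467.016823
2500.0,7.7,8.0,34.0,1035.030063,2454.416581
2500.0,7.7,8.0,38.0,1020.977938,2442.171099
2500.0,7.7,14.0,30.0,1090.321941,2439.915319
2500.0,7.7,14.0,34.0,1064.060268,2425.472022
2500.0,7.7,14.0,38.0,1047.185352,2411.312751
2500.0,7.7,20.0,30.0,1116.270444,2411.008553
2500.0,7.7,20.0,34.0,1086.417530,2394.361487
2500.0,7.7,20.0,38.0,1066.269706,2377.955539
2500.0,8.0,8.0,30.0,501.788838,2365.865809
2500.0,8.0,8.0,34.0,487.884044,2346.140502
2500.0,8.0,8.0,38.0,478.356793,2326.565171
2500.0,8.0,14.0,30.0,510.524290,2327.866745
2500.0,8.0,14.0,34.0,494.635102,2304.978042
2500.0,8.0,14.0,38.0,483.277973,2282.273149
2500.0,8.0,20.0,30.0,514.945974,2285.526238
2500.0,8.0,20.0,34.0,496.889372,2259.176200
2500.0,8.0,20.0,38.0,483.516399,2233.089947
2500.0,8.3,8.0,30.0,227.191985,2226.774822
2500.0,8.3,8.0,34.0,218.640602,2195.763677
2500.0,8.3,8.0,38.0,212.197090,2165.136293
2500.0,8.3,14.0,30.0,226.250239,2170.432792
2500.0,8.3,14.0,34.0,216.605055,2135.374124
2500.0,8.3,14.0,38.0,209.148223,2100.921696
2500.0,8.3,20.0,30.0,222.723437,2108.635811
2500.0,8.3,20.0,34.0,211.990669,2069.592458
2500.0,8.3,20.0,38.0,203.528735,2031.442300
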