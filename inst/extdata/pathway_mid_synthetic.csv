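"year","co2","ch4","n2o"
1765,278,722,270
1775,279.53,730.4,270.7
1785,281.11,737.5,271.3
1795,282.47,744.1,271.9
1805,283.37,750.8,272.4
1815,283.69,758.3,273
1825,283.76,767.2,273.5
1835,283.9,778.2,274.1
1845,284.46,791.9,274.7
1855,285.72,808.9,275.4
1865,287.51,828.6,276.2
1875,289.69,851.5,277.1
1885,292.12,877.9,278.1
1895,294.7,908.2,279.3
1905,297.2,941.6,280.7
1915,299.21,972.4,282
1925,301.27,1006.1,283.6
1935,304.05,1049.3,285.6
1945,308.2,1108.9,288.3
1955,314.37,1193.3,291.9
1965,322.75,1309.8,296.1
1975,333.13,1444.3,301
1985,345.42,1580.3,306.5
1995,360.39,1701.3,312.7
2005,379.06,1792.7,320
2015,400.88,1853.2,329.1
2025,423.25,1877.7,336.4
2035,447.93,1872.3,343.2
2045,474.91,1848.4,349.9
2055,497.95,1812.9,356.3
2065,517.05,1754.1,361.9
2075,528.86,1684.6,366.5
2085,534.28,1621.5,369.9
2095,536.78,1581.8,371.8
2105,539.29,1576,372
2115,541.16,1576,372
2125,542.27,1576,372
2135,542.81,1576,372
2145,542.99,1576,372
2155,543,1576,372
2165,543,1576,372
2175,543,1576,372
2185,543,1576,372
2195,543,1576,372
2205,543,1576,372
2215,543,1576,372
2225,543,1576,372
2235,543,1576,372
2245,543,1576,372
2255,543,1576,372
2265,543,1576,372
2275,543,1576,372
2285,543,1576,372
2295,543,1576,372
2300,543,1576,372
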