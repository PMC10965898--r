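year,x,y
1950,50,0.44
1951,51,0.47
1952,52,0.47
1953,53,0.59
1954,54,0.66
1955,55,0.73
1956,56,0.81
1957,57,0.88
1958,58,1.06
1959,59,1.2
1960,60,1.35
1961,61,1.49
1962,62,1.61
1963,63,2.12
1964,64,11.9
1965,65,12.4
1966,66,14.2
1967,67,15.9
1968,68,18.2
1969,69,21.2
1970,70,4.3
1971,71,2.4
1972,72,2.7
1973,73,2.9
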