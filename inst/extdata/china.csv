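year,x,y
1940,40,1.62
1941,41,1.63
1942,42,1.90
1943,43,2.64
1944,44,2.05
1945,45,2.13
1946,46,1.94
1947,47,15.50
1948,48,364.00
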