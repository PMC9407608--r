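sparsity,T0,T1,T2,T3,T4,T5,T6
0.2,0.2463,0.2382,0.2417,0.229,0.219,0.2268,0.2251
0.25,0.2641,0.2604,0.2623,0.2546,0.239,0.251,0.2544
0.3,0.2704,0.2697,0.2702,0.2658,0.252,0.2624,0.2687
0.35,0.2687,0.269,0.2671,0.2671,0.2513,0.2618,0.2622
0.4,0.2596,0.2609,0.257,0.2606,0.248,0.2563,0.2609
0.45,0.2472,0.2477,0.2441,0.2487,0.2394,0.2435,0.2556
0.5,0.2316,0.2314,0.2281,0.2328,0.2259,0.2282,0.2395
0.55,0.2137,0.213,0.2102,0.2144,0.2096,0.2104,0.2197
0.6,0.1933,0.1927,0.1909,0.1937,0.1896,0.1908,0.1977
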