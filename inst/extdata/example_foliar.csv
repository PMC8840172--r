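N,P,K,Ca,Mg,Cu,Fe,Mn,Zn,B
24.813,2.137,27.505,17.234,2.345,9.191,69.4,65.753,46.993,34.681
30.627,4.186,29.184,22.822,4.293,7.184,94.411,91.539,44.961,22.953
26.276,3.216,23.534,15.242,7.737,6.858,75.273,58.164,21.422,32.924
31.426,4.403,27.745,24.805,7.568,5.793,86.026,88.162,34.199,25.089
28.541,2.476,24.354,18.57,5.997,7.842,76.789,86.071,18.482,35.193
32.815,0.668,22.597,17.279,4.599,5.695,75.308,65.651,22.74,32.836
32.534,2.156,25.629,21.877,7.323,5.432,82.667,89.271,26.873,41.079
28.214,3.805,29.445,21.293,3.411,9.903,74.999,90.313,25.451,39.458
28.549,4.109,21.874,21.67,3.512,6.944,67.65,97.956,21.113,42.244
25.811,4.134,18.346,19.272,5.497,6.587,42.911,78.003,20.854,35.287
25.316,3.837,23.902,19.623,3.915,6.1,73.458,88.794,26.954,33.423
35.574,2.11,26.767,23.493,4.87,9.197,95.176,79.037,87.254,35.437
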