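wavelength_nm,value
400,145.34442
410,143.56098
420,141.84163
430,140.18261
440,138.58047
450,137.03203
460,135.53437
470,134.08476
480,132.68069
490,131.31983
500,130
510,128.71918
520,127.47549
530,126.26716
540,125.09256
550,123.95014
560,122.83845
570,121.75616
580,120.70197
590,119.6747
600,118.67322
610,117.69647
620,116.74345
630,115.8132
640,114.90485
650,114.01754
660,113.15048
670,112.3029
680,111.47408
690,110.66335
700,109.87005
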