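wavelength_nm,value
400,223296
410,303956
420,407560
430,528600
440,413280
450,103292
460,46000
470,33500
480,27000
490,23000
500,20932
510,20035
520,24202
530,32700
540,46592
550,53412
560,53788
570,45072
580,37020
590,28324
600,14677
610,9443
620,6509
630,5148
640,4345
650,3750
660,3226
670,2795
680,2407
690,2051
700,1794
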