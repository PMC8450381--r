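wavelength_nm,value
400,1.95
410,1.8553554
420,1.7706638
430,1.6948795
440,1.6270712
450,1.5664298
460,1.5123315
470,1.4645643
480,1.4238892
490,1.3930081
500,1.3773963
510,1.3843819
520,1.4185963
530,1.4745751
540,1.5323095
550,1.5630576
560,1.5451815
570,1.4784604
580,1.3840875
590,1.2903519
600,1.2167958
610,1.1683973
620,1.1400135
630,1.1237723
640,1.1136162
650,1.106215
660,1.1001259
670,1.0948173
680,1.0900976
690,1.0858799
700,1.0821066
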