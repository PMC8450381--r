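wavelength_nm,value
400,266232
410,466840
420,480360
430,246072
440,102580
450,62816
460,44480
470,33209
480,26629
490,23685
500,20932
510,25773
520,32851
530,39036
540,53236
550,43016
560,32613
570,44496
580,50104
590,14400
600,3200
610,1506
620,942
630,610
640,442
650,368
660,319
670,294
680,277
690,276
700,290
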