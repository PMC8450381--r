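wavelength_nm,value
400,228.82749
410,224.11528
420,219.69576
430,215.54819
440,211.65387
450,207.99592
460,204.55911
470,201.32965
480,198.29503
490,195.4439
500,192.76596
510,190.25183
520,187.89299
530,185.68169
540,183.61087
550,181.67411
560,179.86558
570,178.17998
580,176.6125
590,175.1588
600,173.81497
610,172.57747
620,171.44316
630,170.40923
640,169.47322
650,168.63297
660,167.88664
670,167.23266
680,166.66976
690,166.19694
700,165.81346
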