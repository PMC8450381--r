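wavelength_nm,value
400,1.7763568e-15
410,4.1772367e-14
420,8.4207815e-13
430,1.4551915e-11
440,2.1557201e-10
450,2.7375938e-09
460,2.9802322e-08
470,2.781222e-07
480,2.2249776e-06
490,1.5258789e-05
500,8.9705474e-05
510,0.00045208726
520,0.001953125
530,0.0072333962
540,0.022964601
550,0.0625
560,0.14581613
570,0.29163226
580,0.5
590,0.73486725
600,0.92587471
610,1
620,0.92587471
630,0.73486725
640,0.5
650,0.29163226
660,0.14581613
670,0.0625
680,0.022964601
690,0.0072333962
700,0.001953125
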