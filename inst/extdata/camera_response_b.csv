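wavelength_nm,value
400,0.0625
410,0.14581613
420,0.29163226
430,0.5
440,0.73486725
450,0.92587471
460,1
470,0.92587471
480,0.73486725
490,0.5
500,0.29163226
510,0.14581613
520,0.0625
530,0.022964601
540,0.0072333962
550,0.001953125
560,0.00045208726
570,8.9705474e-05
580,1.5258789e-05
590,2.2249776e-06
600,2.781222e-07
610,2.9802322e-08
620,2.7375938e-09
630,2.1557201e-10
640,1.4551915e-11
650,8.4207815e-13
660,4.1772367e-14
670,1.7763568e-15
680,6.475537e-17
690,2.0236053e-18
700,5.4210109e-20
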