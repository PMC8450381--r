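wavelength_nm,value
400,2.781222e-07
410,2.2249776e-06
420,1.5258789e-05
430,8.9705474e-05
440,0.00045208726
450,0.001953125
460,0.0072333962
470,0.022964601
480,0.0625
490,0.14581613
500,0.29163226
510,0.5
520,0.73486725
530,0.92587471
540,1
550,0.92587471
560,0.73486725
570,0.5
580,0.29163226
590,0.14581613
600,0.0625
610,0.022964601
620,0.0072333962
630,0.001953125
640,0.00045208726
650,8.9705474e-05
660,1.5258789e-05
670,2.2249776e-06
680,2.781222e-07
690,2.9802322e-08
700,2.7375938e-09
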