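wavelength_nm,value
400,2.3194176
410,2.0284406
420,1.7782591
430,1.5631534
440,1.3782059
450,1.2191884
460,1.0824653
470,0.96491111
480,0.86383817
490,0.77693584
500,0.70221735
510,0.63797452
520,0.58273864
530,0.53524692
540,0.49441362
550,0.45930521
560,0.42911907
570,0.40316507
580,0.38084986
590,0.36166328
600,0.3451667
610,0.33098296
620,0.3187878
630,0.30830243
640,0.29928712
650,0.29153578
660,0.28487118
670,0.27914097
680,0.27421415
690,0.26997808
700,0.26633591
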