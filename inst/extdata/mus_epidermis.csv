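wavelength_nm,value
400,341.67565
410,333.73186
420,326.28469
430,319.29733
440,312.7367
450,306.57298
460,300.77927
470,295.33126
480,290.2069
490,285.38621
500,280.85106
510,276.58496
520,272.57288
530,268.80118
540,265.2574
550,261.9302
560,258.80926
570,255.88516
580,253.14934
590,250.59401
600,248.21211
610,245.99725
620,243.94364
630,242.0461
640,240.29997
650,238.70112
660,237.24592
670,235.93117
680,234.75415
690,233.71256
700,232.80453
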