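wavelength_nm,value
400,142.78552
410,131.51452
420,121.37348
430,112.22613
440,103.95527
450,96.459779
460,89.652077
470,83.456097
480,77.805557
490,72.642535
500,67.916269
510,63.582156
520,59.600898
530,55.937788
540,52.562101
550,49.446571
560,46.566951
570,43.901632
580,41.431315
590,39.138731
600,37.008397
610,35.026407
620,33.180247
630,31.458637
640,29.851394
650,28.349308
660,26.944035
670,25.628008
680,24.39435
690,23.236808
700,22.14968
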