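# Synthetic compilation of whole-blood absorption coefficients (mm^-1) for
# fully oxygenated (HbO2) and fully deoxygenated (Hb) blood at a hemoglobin
# concentration of 150 g/L (molar mass 64500 g/mol), constructed by
# piecewise-linear interpolation of approximate molar extinction anchor
# values reproducing the canonical spectral features (Soret band, the
# 540/577 nm HbO2 double peak, the 555 and 760 nm Hb peaks, isosbestic
# points near 500, 570 and 800 nm). Synthetic stand-in for a published
# tabulation; adequate for simulation studies, not for clinical oximetry.
wavelength_nm,mu_a_HbO2_mm,mu_a_Hb_mm
400,142.563217,119.571637
405,171.35517,132.800257
410,249.985773,162.76385
415,279.523121,188.490687
420,252.748875,219.548811
425,188.490687,250.606936
430,131.729287,282.73603
435,80.322736,269.884392
440,54.930042,250.606936
445,37.483943,171.35517
450,33.63702,55.311307
455,25.703275,45.516217
460,23.818369,38.554913
465,20.800643,34.003291
470,17.782918,29.45167
475,16.021173,25.971018
480,14.259428,22.490366
485,13.470926,19.277457
490,12.682424,16.064547
495,11.945597,13.617917
500,11.20877,11.171286
505,10.968605,11.877591
510,10.72844,12.583895
515,11.844123,14.19035
520,12.959806,15.796805
525,17.178088,17.804873
530,21.39637,19.812941
535,24.951722,21.954881
540,28.507074,24.096821
545,27.577473,25.971018
550,23.034419,27.845215
555,19.545199,29.45167
560,17.463769,28.802662
565,18.474229,26.774245
570,23.826936,24.135376
575,29.987155,22.222624
580,26.829936,19.812941
585,15.529062,17.671002
590,7.710983,15.167074
595,3.748394,11.780668
600,1.713552,7.859312
605,1.259996,7.011104
610,0.80644,6.162896
615,0.655434,5.610008
620,0.504427,5.057119
625,0.415536,4.550818
630,0.326646,4.044517
635,0.281665,3.565258
640,0.236684,3.086
645,0.216871,2.547034
650,0.197058,2.008068
655,0.184207,1.868039
660,0.171355,1.72801
665,0.164394,1.612345
670,0.157433,1.49668
675,0.153149,1.393064
680,0.148865,1.289448
685,0.148329,1.194131
690,0.147794,1.098815
695,0.151542,1.029737
700,0.155291,0.96066
705,0.161716,0.892653
710,0.168142,0.824647
715,0.177246,0.76735
720,0.186349,0.710053
725,0.197594,0.650079
730,0.208839,0.590104
735,0.223833,0.593853
740,0.238826,0.597601
745,0.258104,0.674979
750,0.277381,0.752356
755,0.294517,0.846066
760,0.313794,0.862131
765,0.332001,0.792518
770,0.348065,0.702556
775,0.36413,0.639101
780,0.380194,0.575646
785,0.39251,0.526382
790,0.404827,0.477117
795,0.420891,0.442578
800,0.436956,0.408039
805,0.449807,0.395991
810,0.462659,0.383943
815,0.476582,0.377785
820,0.490504,0.371627
825,0.504695,0.371493
830,0.518885,0.371359
835,0.533075,0.371225
840,0.547266,0.371091
845,0.556637,0.375509
850,0.566008,0.379927
855,0.575379,0.384344
860,0.58475,0.388762
865,0.59305,0.39077
870,0.60135,0.392778
875,0.60965,0.394786
880,0.61795,0.396794
885,0.62384,0.399606
890,0.62973,0.402417
895,0.635621,0.405228
900,0.641511,0.408039
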