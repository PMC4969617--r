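wavelength_nm,n,k
381.49,1.46,1.933
397.39,1.47,1.952
413.28,1.46,1.958
430.50,1.45,1.948
450.85,1.38,1.914
471.42,1.31,1.849
495.94,1.04,1.833
520.94,0.62,2.081
548.60,0.43,2.455
582.09,0.29,2.863
616.84,0.21,3.272
659.49,0.14,3.697
704.46,0.13,4.103
755.99,0.14,4.542
821.09,0.16,5.083
891.97,0.17,5.663
983.92,0.22,6.350
1087.58,0.27,7.150
1215.53,0.35,8.145
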