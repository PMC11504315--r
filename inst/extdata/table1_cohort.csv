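patient_id,age,psa,pathologic_gleason,stage,recurrence,time_to_recurrence
PCa#1,66,11.98,7 (4 + 3),pT2c pNx pMx,-,
PCa#2,58,5,7 (3 + 4),pT2c pNx pMx,-,
PCa#4,56,2.15,7 (4 + 3),pT3a pN0 pMx,yes,4
PCa#7,69,4.72,7 (4 + 3),pT3b pN0 pMx,yes,6
PCa#8,71,14,7 (3 + 4),pT2c pNx pMx,-,
PCa#9,69,18.5,7 (3 + 4),pT3a pN0 pMx,yes,12
PCa#10,75,10.25,7 (3 + 4),pT2c pNx pMx,yes,36
PCa#12,64,1.79,7 (3 + 4),pT2c pNx pMx,-,
PCa#13,55,6.12,6 (3 + 3),pT2 pNx pMx,-,
PCa#14,69,7.36,6 (3 + 3),pT2c pNx pMx,-,
PCa#15,60,5.9,7 (4 + 3),pT2c pN0 pMx,-,
PCa#16,67,7.9,7 (3 + 4),pT2a pNx pMx,-,
PCa#18,74,6.2,7 (4 + 3),pT2c pN0 pMx,-,
PCa#20,75,4.88,7 (3 + 4),pT3a pN0 pMx,-,
PCa#23,75,6.3,7 (4 + 3),pT2c pNx pMx,yes,4
PCa#31,75,16.5,7 (3 + 4),pT2c pN0 pMx,-,
PCa#33,63,5.36,7 (3 + 4),pT2c pNx pMx,-,
PCa#34,70,18.04,7 (3 + 4),pT2c pN0 pMx,-,
PCa#35,68,5.75,7 (4 + 3),pT3b pN0 pMx,yes,7
PCa#36,63,14,7 (3 + 4),pT2c pN0 pMx,-,
PCa#40,74,8.4,7 (3 + 4),pT2c pNx pMx,-,
PCa#41,69,6,7 (4 + 3),pT2c pNx pMx,yes,7
PCa#42,78,15,7 (4 + 3),pT3a pNx pMx,-,
PCa#43,67,5.5,7 (3 + 4),pT2c pN0 pMx,-,
PCa#44,67,13.5,7 (4 + 3),pT2c pN0 pMx,-,
PCa#45,69,11.3,9 (4 + 5),pT3b pN0 pMx,yes,8
PCa#46,70,8.68,7 (3 + 4),pT2c pN0 pMx,-,
PCa#48,61,18,7 (4 + 3),pT3a pN0 pMx,-,
PCa#49,65,6.6,7 (4 + 3),pT2c pN0 pMx,-,
PCa#50,50,11,7 (3 + 4),pT2c pNx pMx,-,
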