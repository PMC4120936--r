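participant_id,rank,species_code
P01,1,EG
P01,2,BD
P01,3,SM
P01,4,SP
P01,5,SA
P02,1,EG
P02,2,BD
P02,3,SM
P02,4,PL
P03,1,EG
P03,2,GP
P03,3,LG
P03,4,SM
P04,1,SM
P04,2,PL
P04,3,EG
P05,1,EG
P05,2,SA
P05,3,SM
P05,4,BD
P05,5,PL
P06,1,EG
P06,2,BD
P06,3,LG
P06,4,SM
P06,5,SA
P07,1,SP
P07,2,PL
P07,3,EG
P07,4,BuC
P07,5,SA
P07,6,LG
P07,7,SM
P07,8,BD
P07,9,PS
P07,10,CB
P08,1,SM
P08,2,SA
P08,3,PL
P09,1,SA
P09,2,EG
P09,3,BD
P09,4,PL
P09,5,SM
P10,1,SM
P10,2,EG
P10,3,PL
P10,4,BD
P10,5,SA
P11,1,BD
P11,2,SM
P11,3,EG
P11,4,PL
P12,1,SM
P12,2,BD
P12,3,EG
P12,4,PS
P13,1,SM
P13,2,BD
P13,3,PL
P13,4,EG
P14,1,EG
P14,2,SA
P14,3,PL
P14,4,LG
P14,5,SM
P14,6,PS
P15,1,BD
P15,2,PL
P16,1,EG
P16,2,SM
P16,3,SA
P16,4,PL
P16,5,BD
P16,6,LG
P16,7,SP
P17,1,EG
P17,2,SM
P17,3,PL
P18,1,LG
P18,2,EG
P18,3,PL
P18,4,SM
P18,5,BD
P18,6,MO
P18,7,SP
P18,8,SA
P18,9,KS
P19,1,SM
P19,2,EG
P19,3,PL
P19,4,BD
P19,5,LG
P19,6,SA
P19,7,KS
P19,8,PS
P19,9,CB
P20,1,SM
P20,2,EG
P20,3,SP
P20,4,BD
P20,5,SA
P20,6,LG
P20,7,PL
P20,8,KS
P21,1,EG
P21,2,PL
P21,3,BD
P21,4,SM
P21,5,KS
P21,6,SP
P21,7,SA
P22,1,EG
P22,2,PL
P22,3,LG
P22,4,SP
P22,5,BuC
P23,1,EG
P23,2,LG
P23,3,BD
P23,4,SP
P24,1,SM
P24,2,BD
P25,1,EG
P25,2,PL
P25,3,KS
P26,1,PL
P26,2,SM
P27,1,KS
P27,2,SM
P27,3,PS
P28,1,EG
P28,2,SM
P28,3,PL
P28,4,LG
P28,5,BD
P29,1,EG
P29,2,BD
P29,3,SM
P29,4,LG
P29,5,SA
P29,6,PL
P29,7,SP
P29,8,PS
P29,9,KS
P29,10,CB
P30,1,LG
P30,2,SA
P30,3,EG
P31,1,BD
P31,2,EG
P32,1,SM
P32,2,BD
P32,3,BeC
P32,4,EG
P32,5,BuC
P32,6,SA
P32,7,LG
P33,1,EG
P33,2,PL
P34,1,LG
P34,2,SM
P34,3,BD
P34,4,KS
P34,5,EG
P34,6,SA
P34,7,PL
P34,8,PS
P34,9,SP
P34,10,CB
P34,11,GP
P34,12,MO
P35,1,PL
P35,2,SM
P35,3,EG
P35,4,CB
P35,5,BD
P35,6,SA
P35,7,MO
P36,1,SM
P36,2,EG
P36,3,BD
P36,4,LG
P36,5,PL
P37,1,LG
P37,2,SM
P37,3,PL
P37,4,SP
P38,1,EG
P38,2,SM
P38,3,PL
P38,4,PS
P39,1,PL
P39,2,EG
P39,3,SM
P39,4,SA
P39,5,LG
P39,6,BD
P40,1,LG
P40,2,PL
P40,3,EG
P40,4,BD
P40,5,SA
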