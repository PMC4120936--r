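id,sex,age_years,migration_status
P01,female,18.7083002012223,permanent
P02,female,17.087297992780805,permanent
P03,female,16.412780451588333,none
P04,female,18.504242804832757,permanent
P05,female,17.65954063553363,temporary
P06,female,22.41770062595606,none
P07,female,38.83139501325786,none
P08,female,25.836113640107214,permanent
P09,female,29.418897214345634,permanent
P10,female,34.97585366014391,none
P11,female,59.44868696387857,none
P12,female,40.093139675445855,none
P13,female,56.7566420789808,none
P14,female,57.0011271443218,none
P15,female,41.79017898160964,none
P16,female,74.70330119132996,none
P17,female,72.21733077894896,none
P18,female,72.52672005444765,none
P19,female,79.5954444585368,none
P20,female,68.76878414303064,none
P21,male,19.274182186461985,temporary
P22,male,18.268215051852167,none
P23,male,17.018021197989583,none
P24,male,18.307578277774155,none
P25,male,18.846097287721932,none
P26,male,29.750682073645294,temporary
P27,male,20.273744072765112,permanent
P28,male,25.682541001588106,temporary
P29,male,28.176068356260657,temporary
P30,male,28.26560941990465,temporary
P31,male,47.50282812863588,none
P32,male,47.85375785082579,none
P33,male,45.22983790375292,none
P34,male,45.97571728751063,none
P35,male,47.07691153977066,none
P36,male,72.03010224737227,none
P37,male,70.26700974442065,none
P38,male,72.62462737504393,none
P39,male,75.51329575944692,none
P40,male,76.27289214171469,none
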