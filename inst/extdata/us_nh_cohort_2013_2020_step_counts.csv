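bin,n_residents,n_admission_episodes,total_days,unenrolled_days,enrolled_days,snf_days,hospital_days,observable_days,n_residents_observable,n_admission_episodes_observable,n_observable_episodes
1-30,12336061,18535715,459832789,254994642,204838147,172972223,10300179,28938337,1275260,1410776,1434351
31-60,7271139,9394124,207197264,101428163,105769101,70176713,3557164,32781689,1431592,1547353,1585433
61-100,4556953,5197752,171031431,79405849,91625582,41584448,2431045,48040893,1478432,1570744,1629173
101+,3317609,3570436,1847841777,781205118,1066636659,101288771,12724497,953985923,1861440,1961682,3411082
all,12336061,18535715,2685903261,1217033772,1468869489,386022155,29012885,1063746842,2617363,2945832,4711549
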