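pair_no,functional_group,source,target,n_fish,n_crustacean,n_insect,taxon,example_species,known_ug_L,pred_min_ug_L,pred_max_ug_L,ex_n_over,ex_n_under,ex_decision,sp_n_over,sp_n_under,sp_n_nd
1,ester_phosphate,Acephate,Profenofos,1,3,1,fish,Gambusia affinis,3.48e2,1.82e3,5.79e3,0,3,under,0,1,0
1,ester_phosphate,Acephate,Profenofos,1,3,1,crustacean,Americamysis bahia,2.37,7.85e1,,0,1,under,0,3,0
1,ester_phosphate,Acephate,Profenofos,1,3,1,insect,Culex quinquefasciatus,1.18e1,6.84e-2,2.18e-1,3,0,over,1,0,0
2,ester_phosphate,Dichlorvos,Profenofos,2,4,3,fish,Gambusia affinis,3.48e2,7.57e1,2.91e3,5,7,under,0,2,0
2,ester_phosphate,Dichlorvos,Profenofos,2,4,3,crustacean,Americamysis bahia,1.71,8.93e-2,5.72,2,4,under,2,2,0
2,ester_phosphate,Dichlorvos,Profenofos,2,4,3,insect,Culex pipiens ssp. Pallens,7.45e1,1.85,2.56e1,8,0,over,2,1,0
3,carbamate,Propoxur,Carbaryl,4,1,1,fish,Oncorhynchus mykiss,1.21e3,6.50e3,,0,1,under,2,2,0
3,carbamate,Propoxur,Carbaryl,4,1,1,crustacean,Daphnia magna,2.07e2,8.47e1,2.17e2,3,1,over,1,0,0
3,carbamate,Propoxur,Carbaryl,4,1,1,insect,Aedes aegypti,7.08e2,3.21e2,8.22e2,2,2,nd,0,0,1
4,carbamate,Aminocarb,Carbaryl,4,1,1,fish,Salvelinus fontinalis,1.88e3,7.09e2,,1,0,over,2,2,0
4,carbamate,Aminocarb,Carbaryl,4,1,1,crustacean,Gammarus pseudolimnaeus,1.53e1,6.39e1,1.15e2,0,4,under,0,1,0
4,carbamate,Aminocarb,Carbaryl,4,1,1,insect,Pteronarcella badia,1.53e1,3.29,5.88,4,0,over,1,0,0
5,thiophosphate,Dimethoate,Malathion,3,2,1,fish,Cyprinus carpio,2.65e3,5.80e1,7.03e2,2,0,over,2,0,1
5,thiophosphate,Dimethoate,Malathion,3,2,1,crustacean,Daphnia magna,7.28,3.51e1,2.12e2,0,3,under,1,1,0
5,thiophosphate,Dimethoate,Malathion,3,2,1,insect,Aedes aegypti,1.06e2,3.56e1,2.60e3,1,5,under,0,1,0
6,thiophosphate,Dimethoate,Chlorpyrifos,4,1,1,fish,Oreochromis niloticus,1.25e2,3.63,,1,0,over,2,2,0
6,thiophosphate,Dimethoate,Chlorpyrifos,4,1,1,crustacean,Daphnia magna,8.04,1.82,2.67e1,2,2,nd,0,0,1
6,thiophosphate,Dimethoate,Chlorpyrifos,4,1,1,insect,Aedes aegypti,7.02,4.96,7.28e1,1,3,under,0,1,0
7,thiophosphate,Malathion,Methyl parathion,1,2,1,fish,Pimephales promelas,7.14e3,8.41e2,1.31e3,2,0,over,1,0,0
7,thiophosphate,Malathion,Methyl parathion,1,2,1,crustacean,Americamysis bahia,6.92e-1,9.08e-1,,0,1,under,0,2,0
7,thiophosphate,Malathion,Methyl parathion,1,2,1,insect,Culex pipiens ssp.,3.07,8.21,1.28e1,0,2,under,0,1,0
8,thiophosphate,Malathion,Diazinon,3,2,1,fish,Channa punctata,1.44e3,4.25e2,5.41e2,2,0,over,3,0,0
8,thiophosphate,Malathion,Diazinon,3,2,1,crustacean,Daphnia magna,1.22,1.74,2.30,0,3,under,0,2,0
8,thiophosphate,Malathion,Diazinon,3,2,1,insect,Culex quinquefasciatus,6.67,9.10,1.53e1,0,6,under,0,1,0
9,thiophosphate,Malathion,Fenthion,1,1,10,fish,Pimephales promelas,2.75e3,2.28e2,2.43e3,10,0,over,1,0,0
9,thiophosphate,Malathion,Fenthion,1,1,10,crustacean,Americamysis bahia,2.65e-1,1.58e-1,1.69,1,9,under,0,1,0
9,thiophosphate,Malathion,Fenthion,1,1,10,insect,Aedes aegypti,2.35e1,1.04e1,,1,0,over,5,5,0
10,thiophosphate,Malathion,Chlorpyrifos,7,2,14,fish,Lepomis macrochirus,5.72,2.86e-1,9.82,22,6,over,6,1,0
10,thiophosphate,Malathion,Chlorpyrifos,7,2,14,crustacean,Americamysis bahia,4.00e-2,1.90e-2,1.42,5,93,under,0,2,0
10,thiophosphate,Malathion,Chlorpyrifos,7,2,14,insect,Aedes aegypti,7.02,1.05,4.29,14,0,over,7,7,0
11,thiophosphate,Methyl parathion,Chlorpyrifos,3,4,1,fish,Lepomis macrochirus,5.72,3.22e2,1.38e3,0,4,under,0,3,0
11,thiophosphate,Methyl parathion,Chlorpyrifos,3,4,1,crustacean,Americamysis bahia,4.00e-2,1.65e-2,6.46e-2,2,1,over,3,1,0
11,thiophosphate,Methyl parathion,Chlorpyrifos,3,4,1,insect,Culex pipiens ssp.,1.04,2.05e-2,3.45e-1,12,0,over,1,0,0
12,thiophosphate,Diazinon,Fenthion,3,1,1,fish,Oncorhynchus mykiss,7.95e2,5.88e1,,1,0,over,3,0,0
12,thiophosphate,Diazinon,Fenthion,3,1,1,crustacean,Americamysis bahia,2.65e-1,9.99e-1,1.19,0,3,under,0,1,0
12,thiophosphate,Diazinon,Fenthion,3,1,1,insect,Culex pipiens ssp.,5.07,1.29e1,1.53e1,0,3,under,0,1,0
13,thiophosphate,Diazinon,Chlorpyrifos,6,3,2,fish,Lepomis macrochirus,5.72,1.80,8.05e1,1,5,under,1,5,0
13,thiophosphate,Diazinon,Chlorpyrifos,6,3,2,crustacean,Americamysis bahia,4.00e-2,4.61e-2,1.26,0,12,under,2,1,0
13,thiophosphate,Diazinon,Chlorpyrifos,6,3,2,insect,Culex pipiens ssp.,1.04,5.13e-1,2.23e1,3,15,under,1,1,0
14,thiophosphate,Fenthion,Chlorpyrifos,5,1,11,fish,Oncorhynchus mykiss,1.82e1,5.86e1,1.77e2,0,11,under,0,5,0
14,thiophosphate,Fenthion,Chlorpyrifos,5,1,11,crustacean,Americamysis bahia,4.00e-2,2.67e-3,4.73e-2,52,3,over,1,0,0
14,thiophosphate,Fenthion,Chlorpyrifos,5,1,11,insect,Aedes aegypti,7.02,4.86e-1,2.84,5,0,over,9,2,0
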