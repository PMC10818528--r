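name,cas,functional_group,taxon,n,min_mg_L,max_mg_L
Acephate,30560-19-1,ester_phosphate,fish,12,1.46e-3,3.08e3
Acephate,30560-19-1,ester_phosphate,crustacean,7,3.50e-1,2.35e3
Acephate,30560-19-1,ester_phosphate,insect,9,1.14e-1,6.50e2
Acephate,30560-19-1,ester_phosphate,amphibian,2,6.43e3,8.82e3
Dichlorvos,62-73-7,ester_phosphate,fish,38,6.41e-3,1.67e2
Dichlorvos,62-73-7,ester_phosphate,crustacean,25,1.30e-4,1.29e2
Dichlorvos,62-73-7,ester_phosphate,insect,24,1.00e-4,2.38e2
Dichlorvos,62-73-7,ester_phosphate,amphibian,5,7.80e-1,7.89e1
Methamidophos,10265-92-6,ester_phosphate,fish,8,5.36e1,1.12e2
Methamidophos,10265-92-6,ester_phosphate,crustacean,4,1.61e-6,1.46
Methamidophos,10265-92-6,ester_phosphate,amphibian,1,2.72e1,2.72e1
Mevinphos,7786-34-7,ester_phosphate,fish,12,2.23e-2,4.00e1
Mevinphos,7786-34-7,ester_phosphate,crustacean,9,9.50e-4,1.30e-1
Mevinphos,7786-34-7,ester_phosphate,insect,1,4.95e-3,4.95e-3
Nemacur,22224-92-6,ester_phosphate,fish,3,1.75e-2,1.40e-1
Nemacur,22224-92-6,ester_phosphate,crustacean,6,2.65e-3,1.50e-1
Profenofos,41198-08-7,ester_phosphate,fish,17,2.55e-3,2.02
Profenofos,41198-08-7,ester_phosphate,crustacean,11,4.10e-5,7.71
Profenofos,41198-08-7,ester_phosphate,insect,6,1.18e-2,3.70
Profenofos,41198-08-7,ester_phosphate,amphibian,1,5.80e-1,5.80e-1
Aminocarb,2032-59-9,carbamate,fish,12,5.24e-1,1.00e2
Aminocarb,2032-59-9,carbamate,crustacean,8,1.20e-2,3.27e1
Aminocarb,2032-59-9,carbamate,insect,7,2.25e-2,2.86
Carbaryl,63-25-2,carbamate,fish,60,6.93e-7,1.08e2
Carbaryl,63-25-2,carbamate,crustacean,41,3.75e-3,9.65
Carbaryl,63-25-2,carbamate,insect,42,6.94e-7,4.79
Carbaryl,63-25-2,carbamate,amphibian,17,1.64,5.53e1
Carbofuran,1563-66-2,carbamate,fish,28,4.23e-2,7.90
Carbofuran,1563-66-2,carbamate,crustacean,15,3.32e-4,2.70
Carbofuran,1563-66-2,carbamate,insect,8,1.19e-4,1.59
Carbofuran,1563-66-2,carbamate,amphibian,3,1.12e1,1.13e2
Propoxur,114-26-1,carbamate,fish,12,1.30,4.25e1
Propoxur,114-26-1,carbamate,crustacean,7,1.50e-2,1.43
Propoxur,114-26-1,carbamate,insect,22,1.80e-2,8.00
Aldicarb,116-06-3,carbamate,fish,9,6.56e-2,4.50e1
Aldicarb,116-06-3,carbamate,crustacean,16,1.20e-2,1.73e1
Aldicarb,116-06-3,carbamate,insect,5,2.00e-2,2.80e-1
Methomyl,16752-77-5,carbamate,fish,14,3.40e-1,5.25
Methomyl,16752-77-5,carbamate,crustacean,19,6.40e-3,7.20
Methomyl,16752-77-5,carbamate,insect,4,6.43e-2,8.79e-1
Methomyl,16752-77-5,carbamate,amphibian,3,5.55e1,6.16e2
Oxamyl,23135-22-0,carbamate,fish,6,2.60,2.75e1
Oxamyl,23135-22-0,carbamate,crustacean,4,2.20e-1,2.30e1
Chlorpyrifos,2921-88-2,thiophosphate,fish,40,5.80e-4,5.98e-1
Chlorpyrifos,2921-88-2,thiophosphate,crustacean,47,7.28e-11,4.57e-1
Chlorpyrifos,2921-88-2,thiophosphate,insect,85,5.00e-5,3.80e-1
Chlorpyrifos,2921-88-2,thiophosphate,amphibian,6,1.90e-2,5.62e-1
Diazinon,333-41-5,thiophosphate,fish,53,7.00e-5,4.00e1
Diazinon,333-41-5,thiophosphate,crustacean,20,3.87e-4,1.25
Diazinon,333-41-5,thiophosphate,insect,23,5.67e-4,2.20e-1
Diazinon,333-41-5,thiophosphate,amphibian,5,3.43,1.48e1
EPN,2104-64-5,thiophosphate,fish,11,1.81e-2,4.20e-1
EPN,2104-64-5,thiophosphate,crustacean,6,2.90e-4,4.38e-2
EPN,2104-64-5,thiophosphate,insect,2,1.10e-3,7.40e-3
Fensulfothion,115-90-2,thiophosphate,fish,3,7.20e-2,4.31e1
Fensulfothion,115-90-2,thiophosphate,crustacean,2,1.00e-2,5.07e-2
Fenthion,55-38-9,thiophosphate,fish,21,4.53e-1,3.10
Fenthion,55-38-9,thiophosphate,crustacean,16,1.52e-4,1.80
Fenthion,55-38-9,thiophosphate,insect,57,5.00e-4,1.10
Fenthion,55-38-9,thiophosphate,amphibian,1,9.40e-4,9.40e-4
Methyl parathion,298-00-0,thiophosphate,fish,42,5.00e-3,1.90e1
Methyl parathion,298-00-0,thiophosphate,crustacean,28,2.05e-4,4.00
Methyl parathion,298-00-0,thiophosphate,insect,12,5.40e-4,2.74e-1
Methyl parathion,298-00-0,thiophosphate,amphibian,4,3.70,9.59
Azinphos-methyl,86-50-0,thiophosphate,fish,26,3.60e-4,4.06
Azinphos-methyl,86-50-0,thiophosphate,crustacean,10,1.61e-4,1.38e1
Azinphos-methyl,86-50-0,thiophosphate,insect,6,3.70e-4,8.85e-2
Dimethoate,60-51-5,thiophosphate,fish,26,1.30e-1,4.20e1
Dimethoate,60-51-5,thiophosphate,crustacean,14,2.00e-3,1.50e1
Dimethoate,60-51-5,thiophosphate,insect,13,1.29e-3,9.60
Dimethoate,60-51-5,thiophosphate,amphibian,5,7.82e-3,3.75e1
Disulfoton,298-04-4,thiophosphate,fish,10,3.70e-2,7.20
Disulfoton,298-04-4,thiophosphate,crustacean,3,3.90e-3,1.00e-1
Disulfoton,298-04-4,thiophosphate,insect,1,5.00e-3,5.00e-3
Dyfonate,944-22-9,thiophosphate,fish,5,1.60e-2,1.09
Dyfonate,944-22-9,thiophosphate,crustacean,2,4.90e-4,2.70e-3
Dyfonate,944-22-9,thiophosphate,insect,2,3.90e-2,5.40e-2
Malathion,121-75-5,thiophosphate,fish,72,1.95e-2,1.70e1
Malathion,121-75-5,thiophosphate,crustacean,46,9.70e-5,8.15e1
Malathion,121-75-5,thiophosphate,insect,67,1.00e-3,2.69e1
Malathion,121-75-5,thiophosphate,amphibian,9,5.90e-4,3.32e1
Terbufos,13071-79-9,thiophosphate,fish,8,2.90e-3,1.31e-1
Terbufos,13071-79-9,thiophosphate,crustacean,5,2.97e-4,1.00e-2
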