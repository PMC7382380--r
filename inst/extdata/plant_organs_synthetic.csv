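"plant_id","genotype","condition","experiment","organ","dw_mg","n_pct","c_pct","a15_pct"
"g63_control_1_r1","63","control","1","rosette","200","0.5","40","0.466"
"g63_control_1_r1","63","control","1","stem","1000","0.5","42","0.446"
"g63_control_1_r1","63","control","1","seeds","800","0.5","56","0.491"
"g63_control_1_r2","63","control","1","rosette","230","2.5","40","0.47"
"g63_control_1_r2","63","control","1","stem","1600","2.8","42","0.45"
"g63_control_1_r2","63","control","1","seeds","840","4","55.1","0.49"
"g401_control_1_r1","401","control","1","rosette","250","2.4","40","0.465"
"g401_control_1_r1","401","control","1","stem","1500","2.9","42","0.445"
"g401_control_1_r1","401","control","1","seeds","900","4.3","53.1","0.488"
"g401_control_1_r2","401","control","1","rosette","220","2.6","40","0.468"
"g401_control_1_r2","401","control","1","stem","1450","2.7","42","0.447"
"g401_control_1_r2","401","control","1","seeds","870","4.5","52.3","0.489"
"g63_heat_1_r1","63","heat","1","rosette","170","0.8","40","0.9"
"g63_heat_1_r1","63","heat","1","stem","900","2.6","42","0.55"
"g63_heat_1_r1","63","heat","1","seeds","20","4.9","51.5","0.42"
"g63_heat_1_r2","63","heat","1","rosette","185","0.7","40","0.88"
"g63_heat_1_r2","63","heat","1","stem","950","2.5","42","0.54"
"g63_heat_1_r2","63","heat","1","seeds","22","4.8","52","0.41"
"g401_heat_1_r1","401","heat","1","rosette","200","0.8","40","0.85"
"g401_heat_1_r1","401","heat","1","stem","1100","2.4","42","0.53"
"g401_heat_1_r1","401","heat","1","seeds","18","5","50.2","0.4"
"g401_heat_1_r2","401","heat","1","rosette","190","0.9","40","0.87"
"g401_heat_1_r2","401","heat","1","stem","1050","2.5","42","0.535"
"g401_heat_1_r2","401","heat","1","seeds","0","0","0",""
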