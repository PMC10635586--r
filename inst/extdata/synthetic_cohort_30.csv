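"id","months_since_concussion","rpq_01","rpq_02","rpq_03","rpq_04","rpq_05","rpq_06","rpq_07","rpq_08","rpq_09","rpq_10","rpq_11","rpq_12","rpq_13","rpq_14","rpq_15","rpq_16","imp_appointments","imp_conversations","imp_driving","imp_math","imp_paperwork","imp_planning","imp_other","imp_none","impairment_data_available"
"P00001",43.3,1,0,2,0,0,0,1,0,2,2,0,1,0,0,0,2,0,0,1,0,1,0,0,0,1
"P00002",66,0,0,0,3,3,2,4,1,3,0,2,1,1,0,0,3,1,0,0,0,0,0,0,0,1
"P00003",105.8,0,0,0,4,3,0,1,1,0,0,0,2,0,4,0,1,1,1,0,0,0,1,0,0,1
"P00004",45.5,1,2,2,0,3,1,0,1,0,3,0,1,3,0,3,0,0,1,0,0,0,0,0,0,1
"P00005",49.7,2,0,2,0,0,0,2,1,1,0,0,0,0,1,0,3,0,1,0,0,0,0,1,0,1
"P00006",41.9,0,0,0,2,0,0,1,0,0,0,1,1,0,2,0,0,0,1,0,1,0,1,0,0,1
"P00007",95.2,1,0,2,2,3,3,0,1,0,1,4,2,0,2,0,0,1,0,0,0,0,0,0,0,1
"P00008",19,0,0,1,2,2,0,1,0,1,0,1,0,0,1,0,1,NA,NA,NA,NA,NA,NA,NA,NA,0
"P00009",107.1,2,1,4,0,2,1,0,2,1,2,3,4,1,0,0,2,0,1,0,1,0,0,0,0,1
"P00010",64.1,2,1,4,0,1,0,4,3,4,1,0,0,2,1,1,2,NA,NA,NA,NA,NA,NA,NA,NA,0
"P00011",82.5,0,1,2,0,2,0,3,2,4,4,3,4,0,1,2,4,0,1,1,0,1,1,1,0,1
"P00012",55.2,3,2,3,2,1,0,0,1,2,2,1,2,1,0,3,2,NA,NA,NA,NA,NA,NA,NA,NA,0
"P00013",80.2,1,0,1,0,1,0,0,0,0,0,0,0,1,0,3,2,1,0,0,0,0,0,0,0,1
"P00014",82,0,0,0,2,0,0,1,2,4,2,0,0,0,1,0,4,1,1,1,1,1,0,0,0,1
"P00015",13.2,1,1,1,0,0,2,1,0,1,0,1,2,1,0,3,0,0,0,0,0,1,0,0,0,1
"P00016",46.5,1,1,0,0,1,0,0,0,0,0,0,1,0,0,1,0,1,1,0,0,0,0,0,0,1
"P00017",20.4,2,1,2,2,3,2,3,2,2,1,0,1,1,2,0,3,1,1,0,1,0,0,0,0,1
"P00018",85.2,1,2,3,0,0,0,2,0,2,4,3,3,1,1,1,2,0,1,0,0,0,0,0,0,1
"P00019",111.3,1,4,3,0,0,0,1,1,1,0,0,4,2,0,0,1,0,1,0,0,0,1,0,0,1
"P00020",111.3,3,4,3,4,3,3,1,1,1,2,1,3,3,4,3,0,0,1,0,0,1,0,0,0,1
"P00021",42,0,0,0,0,2,1,1,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0,1
"P00022",94.4,0,0,1,0,1,1,0,0,0,2,3,1,0,0,1,0,0,1,0,1,0,0,0,0,1
"P00023",24.6,0,3,1,0,0,0,4,1,2,1,0,2,3,0,1,2,0,0,0,0,0,0,0,1,1
"P00024",37.9,0,1,0,0,0,0,0,0,0,2,2,4,0,0,0,0,1,1,0,0,0,0,0,0,1
"P00025",74,0,0,1,0,2,2,1,0,1,0,0,0,0,0,0,0,1,0,0,1,1,1,0,0,1
"P00026",26.8,1,2,0,0,0,0,0,0,0,2,1,1,2,0,3,0,NA,NA,NA,NA,NA,NA,NA,NA,0
"P00027",103,0,0,1,2,2,3,0,1,3,1,0,0,2,0,0,0,0,0,0,0,0,1,0,0,1
"P00028",109.5,0,0,1,2,0,0,4,1,4,0,0,0,0,1,1,2,NA,NA,NA,NA,NA,NA,NA,NA,0
"P00029",39,2,2,2,0,1,0,0,0,0,0,0,0,1,0,1,1,1,1,0,0,0,0,0,0,1
"P00030",92.8,0,0,0,0,0,0,0,3,2,0,0,0,0,1,0,4,0,1,0,0,1,1,0,0,1
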