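"patient_id","recipient_age","blood_type","pra","medical_urgency","waiting_time_years","hla_a1","hla_a2","hla_b1","hla_b2","hla_dr1","hla_dr2","predicted_survival","diabetes","prior_solid_organ_transplant","dialysis_years"
"P0001",27.4,"A",0,0,1.104,"A19","A14","B18","B6","DR9","DR1",17.52,0,0,2.14
"P0002",56.1,"A",0,0,0.179,"A4","A19","B1","B30","DR4","DR15",17.26,0,0,0
"P0003",72.1,"B",0,0,2.447,"A4","A15","B25","B20","DR3","DR10",12.6,1,0,0.97
"P0004",9.2,"O",0,0,0.686,"A6","A11","B26","B18","DR5","DR10",14.47,0,0,2.75
"P0005",16.4,"O",0,0,1.494,"A4","A15","B30","B16","DR8","DR14",16.41,0,0,2.03
"P0006",71.3,"A",0,0,1.012,"A17","A18","B29","B10","DR7","DR3",4.04,1,0,5.69
"P0007",45.6,"A",0,0,1.82,"A12","A11","B25","B20","DR11","DR5",11.32,1,0,3.76
"P0008",39.4,"O",67.4,0,1.876,"A7","A10","B25","B3","DR12","DR2",11.47,0,0,2.62
"P0009",43.4,"O",0,0,0.219,"A7","A9","B9","B9","DR11","DR11",13.11,1,0,0.51
"P0010",40.1,"B",0,0,1.411,"A17","A10","B27","B30","DR8","DR3",17.65,0,0,2.29
"P0011",34.5,"B",44.1,0,1.942,"A17","A12","B28","B25","DR3","DR8",13.7,1,0,0
"P0012",34.9,"O",0,0,0.547,"A16","A8","B19","B11","DR15","DR2",12.32,0,0,1.49
"P0013",47.8,"O",0,0,15.046,"A17","A16","B14","B27","DR1","DR11",13.17,0,0,0.79
"P0014",52.8,"O",0,1,1.339,"A7","A11","B4","B6","DR2","DR11",15.35,1,0,0
"P0015",40.6,"O",0,0,0.741,"A6","A7","B22","B28","DR14","DR9",15.17,1,0,4.22
"P0016",19.2,"O",33,0,1.713,"A12","A20","B23","B18","DR5","DR7",15.96,1,0,1.13
"P0017",55.6,"B",0,0,0.294,"A6","A4","B10","B1","DR9","DR14",14.39,0,0,0
"P0018",64.7,"B",17.2,0,0.68,"A11","A17","B21","B3","DR13","DR9",7.61,0,0,0.84
"P0019",30.1,"O",0,0,2.111,"A11","A10","B12","B23","DR6","DR7",20,0,0,0.25
"P0020",55.5,"A",0,0,0.361,"A5","A3","B19","B27","DR14","DR6",11.53,0,0,3.7
"P0021",32.5,"B",0,1,1.822,"A2","A7","B13","B20","DR1","DR3",6.57,0,0,7.98
"P0022",28.7,"O",0,0,2.698,"A10","A10","B8","B26","DR14","DR14",8.46,0,0,4.09
"P0023",37.8,"B",0,0,0.19,"A16","A5","B18","B20","DR14","DR9",9.19,1,0,4.2
"P0024",20.8,"B",15.1,0,0.556,"A3","A13","B13","B1","DR6","DR8",15.04,0,0,5.18
"P0025",34.1,"O",69.3,0,0.272,"A16","A3","B3","B12","DR15","DR12",9.66,0,0,3.4
"P0026",40.9,"O",0,1,2.66,"A11","A9","B19","B29","DR4","DR13",12.35,0,0,6.96
"P0027",6.2,"A",0,0,2.8,"A8","A15","B5","B11","DR15","DR12",20,0,0,0
"P0028",59.8,"B",21.8,0,0.974,"A6","A7","B29","B9","DR7","DR1",7.78,0,0,1.38
"P0029",69.6,"O",0,0,3.932,"A14","A14","B18","B29","DR8","DR2",9.54,1,0,0.78
"P0030",61.6,"O",0,0,0.447,"A7","A11","B21","B17","DR3","DR9",10.39,1,0,2.94
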