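"donor_id","donor_age","blood_type","hla_a1","hla_a2","hla_b1","hla_b2","hla_dr1","hla_dr2","allocation_date"
"D001",37.3,"O","A19","A20","B12","B2","DR14","DR15","2017-12-01"
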