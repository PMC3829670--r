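patient_id,occasion_label,occasion_order,weeks_elapsed,rater,item_id,item_class,scale,value
P001,baseline,0,0,assessor,vas_pain,anamnestic,vas_0_100,20
P001,baseline,0,0,assessor,A01,anamnestic,points_0_4,3
P001,baseline,0,0,assessor,A02,anamnestic,points_0_4,3
P001,baseline,0,0,assessor,A03,anamnestic,points_0_4,3
P001,baseline,0,0,assessor,A04,anamnestic,points_0_4,1
P001,baseline,0,0,assessor,A05,anamnestic,points_0_4,0
P001,baseline,0,0,assessor,C01,clinical,points_0_4,2
P001,baseline,0,0,assessor,C02,clinical,points_0_4,2
P001,baseline,0,0,assessor,C03,clinical,points_0_4,2
P001,baseline,0,0,assessor,C04,clinical,points_0_4,2
P001,baseline,0,0,assessor,C05,clinical,points_0_4,2
P001,baseline,0,0,assessor,C06,clinical,points_0_4,2
P001,baseline,0,0,assessor,C07,clinical,points_0_4,1
P001,baseline,0,0,assessor,C08,clinical,points_0_4,0
P001,EM,1,10,assessor,vas_pain,anamnestic,vas_0_100,3
P001,EM,1,10,assessor,A01,anamnestic,points_0_4,1
P001,EM,1,10,assessor,A02,anamnestic,points_0_4,1
P001,EM,1,10,assessor,A03,anamnestic,points_0_4,0
P001,EM,1,10,assessor,A04,anamnestic,points_0_4,1
P001,EM,1,10,assessor,A05,anamnestic,points_0_4,0
P001,EM,1,10,assessor,C01,clinical,points_0_4,0
P001,EM,1,10,assessor,C02,clinical,points_0_4,0
P001,EM,1,10,assessor,C03,clinical,points_0_4,1
P001,EM,1,10,assessor,C04,clinical,points_0_4,1
P001,EM,1,10,assessor,C05,clinical,points_0_4,0
P001,EM,1,10,assessor,C06,clinical,points_0_4,1
P001,EM,1,10,assessor,C07,clinical,points_0_4,1
P001,EM,1,10,assessor,C08,clinical,points_0_4,1
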