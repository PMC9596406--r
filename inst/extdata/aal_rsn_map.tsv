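region	network
Precentral_L	Sensorymotor
Precentral_R	Sensorymotor
Frontal_Sup_L	Executive Function
Frontal_Sup_R	Executive Function
Frontal_Sup_Orb_L	DMN
Frontal_Sup_Orb_R	DMN
Frontal_Mid_L	Executive Function
Frontal_Mid_R	Executive Function
Frontal_Mid_Orb_L	DMN
Frontal_Mid_Orb_R	DMN
Frontal_Inf_Oper_L	Executive Function
Frontal_Inf_Oper_R	Executive Function
Frontal_Inf_Tri_L	Executive Function
Frontal_Inf_Tri_R	Executive Function
Frontal_Inf_Orb_L	Executive Function
Frontal_Inf_Orb_R	Executive Function
Rolandic_Oper_L	Sensorymotor
Rolandic_Oper_R	Sensorymotor
Supp_Motor_Area_L	Sensorymotor
Supp_Motor_Area_R	Sensorymotor
Olfactory_L	Limbic
Olfactory_R	Limbic
Frontal_Sup_Medial_L	Executive Function
Frontal_Sup_Medial_R	Executive Function
Frontal_Med_Orb_L	DMN
Frontal_Med_Orb_R	DMN
Rectus_L	DMN
Rectus_R	DMN
Insula_L	Executive Function
Insula_R	Executive Function
Cingulum_Ant_L	Executive Function
Cingulum_Ant_R	Executive Function
Cingulum_Mid_L	Executive Function
Cingulum_Mid_R	Executive Function
Cingulum_Post_L	DMN
Cingulum_Post_R	DMN
Hippocampus_L	Limbic
Hippocampus_R	Limbic
ParaHippocampal_L	Limbic
ParaHippocampal_R	Limbic
Amygdala_L	Limbic
Amygdala_R	Limbic
Calcarine_L	Visual I
Calcarine_R	Visual I
Cuneus_L	Visual I
Cuneus_R	Visual I
Lingual_L	Visual I
Lingual_R	Visual I
Occipital_Sup_L	Visual II
Occipital_Sup_R	Visual II
Occipital_Mid_L	Visual II
Occipital_Mid_R	Visual II
Occipital_Inf_L	Visual II
Occipital_Inf_R	Visual II
Fusiform_L	Visual II
Fusiform_R	Visual II
Postcentral_L	Sensorymotor
Postcentral_R	Sensorymotor
Parietal_Sup_L	Visual III
Parietal_Sup_R	Visual III
Parietal_Inf_L	Visual III
Parietal_Inf_R	Visual III
SupraMarginal_L	Visual III
SupraMarginal_R	Visual III
Angular_L	DMN
Angular_R	DMN
Precuneus_L	DMN
Precuneus_R	DMN
Paracentral_Lobule_L	Sensorymotor
Paracentral_Lobule_R	Sensorymotor
Caudate_L	Basal Ganglia
Caudate_R	Basal Ganglia
Putamen_L	Basal Ganglia
Putamen_R	Basal Ganglia
Pallidum_L	Basal Ganglia
Pallidum_R	Basal Ganglia
Thalamus_L	Basal Ganglia
Thalamus_R	Basal Ganglia
Heschl_L	Auditory
Heschl_R	Auditory
Temporal_Sup_L	Auditory
Temporal_Sup_R	Auditory
Temporal_Pole_Sup_L	Limbic
Temporal_Pole_Sup_R	Limbic
Temporal_Mid_L	Auditory
Temporal_Mid_R	Auditory
Temporal_Pole_Mid_L	Limbic
Temporal_Pole_Mid_R	Limbic
Temporal_Inf_L	Auditory
Temporal_Inf_R	Auditory
Cerebelum_Crus1_L	Cerebellum
Cerebelum_Crus1_R	Cerebellum
Cerebelum_Crus2_L	Cerebellum
Cerebelum_Crus2_R	Cerebellum
Cerebelum_3_L	Cerebellum
Cerebelum_3_R	Cerebellum
Cerebelum_4_5_L	Cerebellum
Cerebelum_4_5_R	Cerebellum
Cerebelum_6_L	Cerebellum
Cerebelum_6_R	Cerebellum
Cerebelum_7b_L	Cerebellum
Cerebelum_7b_R	Cerebellum
Cerebelum_8_L	Cerebellum
Cerebelum_8_R	Cerebellum
Cerebelum_9_L	Cerebellum
Cerebelum_9_R	Cerebellum
Cerebelum_10_L	Cerebellum
Cerebelum_10_R	Cerebellum
Vermis_1_2	Cerebellum
Vermis_3	Cerebellum
Vermis_4_5	Cerebellum
Vermis_6	Cerebellum
Vermis_7	Cerebellum
Vermis_8	Cerebellum
Vermis_9	Cerebellum
Vermis_10	Cerebellum
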