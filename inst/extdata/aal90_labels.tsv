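label	cortical
Precentral_L	TRUE
Precentral_R	TRUE
Frontal_Sup_L	TRUE
Frontal_Sup_R	TRUE
Frontal_Sup_Orb_L	TRUE
Frontal_Sup_Orb_R	TRUE
Frontal_Mid_L	TRUE
Frontal_Mid_R	TRUE
Frontal_Mid_Orb_L	TRUE
Frontal_Mid_Orb_R	TRUE
Frontal_Inf_Oper_L	TRUE
Frontal_Inf_Oper_R	TRUE
Frontal_Inf_Tri_L	TRUE
Frontal_Inf_Tri_R	TRUE
Frontal_Inf_Orb_L	TRUE
Frontal_Inf_Orb_R	TRUE
Rolandic_Oper_L	TRUE
Rolandic_Oper_R	TRUE
Supp_Motor_Area_L	TRUE
Supp_Motor_Area_R	TRUE
Olfactory_L	TRUE
Olfactory_R	TRUE
Frontal_Sup_Medial_L	TRUE
Frontal_Sup_Medial_R	TRUE
Frontal_Med_Orb_L	TRUE
Frontal_Med_Orb_R	TRUE
Rectus_L	TRUE
Rectus_R	TRUE
Insula_L	TRUE
Insula_R	TRUE
Cingulum_Ant_L	TRUE
Cingulum_Ant_R	TRUE
Cingulum_Mid_L	TRUE
Cingulum_Mid_R	TRUE
Cingulum_Post_L	TRUE
Cingulum_Post_R	TRUE
Hippocampus_L	FALSE
Hippocampus_R	FALSE
ParaHippocampal_L	TRUE
ParaHippocampal_R	TRUE
Amygdala_L	FALSE
Amygdala_R	FALSE
Calcarine_L	TRUE
Calcarine_R	TRUE
Cuneus_L	TRUE
Cuneus_R	TRUE
Lingual_L	TRUE
Lingual_R	TRUE
Occipital_Sup_L	TRUE
Occipital_Sup_R	TRUE
Occipital_Mid_L	TRUE
Occipital_Mid_R	TRUE
Occipital_Inf_L	TRUE
Occipital_Inf_R	TRUE
Fusiform_L	TRUE
Fusiform_R	TRUE
Postcentral_L	TRUE
Postcentral_R	TRUE
Parietal_Sup_L	TRUE
Parietal_Sup_R	TRUE
Parietal_Inf_L	TRUE
Parietal_Inf_R	TRUE
SupraMarginal_L	TRUE
SupraMarginal_R	TRUE
Angular_L	TRUE
Angular_R	TRUE
Precuneus_L	TRUE
Precuneus_R	TRUE
Paracentral_Lobule_L	TRUE
Paracentral_Lobule_R	TRUE
Caudate_L	FALSE
Caudate_R	FALSE
Putamen_L	FALSE
Putamen_R	FALSE
Pallidum_L	FALSE
Pallidum_R	FALSE
Thalamus_L	FALSE
Thalamus_R	FALSE
Heschl_L	TRUE
Heschl_R	TRUE
Temporal_Sup_L	TRUE
Temporal_Sup_R	TRUE
Temporal_Pole_Sup_L	TRUE
Temporal_Pole_Sup_R	TRUE
Temporal_Mid_L	TRUE
Temporal_Mid_R	TRUE
Temporal_Pole_Mid_L	TRUE
Temporal_Pole_Mid_R	TRUE
Temporal_Inf_L	TRUE
Temporal_Inf_R	TRUE
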