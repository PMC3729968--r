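{
  "default_mode": ["Frontal_Sup_Medial_L", "Frontal_Sup_Medial_R",
                   "Cingulum_Post_L", "Cingulum_Post_R",
                   "Precuneus_L", "Precuneus_R",
                   "Angular_L", "Angular_R"],
  "frontoparietal_left": ["Frontal_Mid_L", "Frontal_Inf_Tri_L", "Parietal_Sup_L"],
  "frontoparietal_right": ["Frontal_Mid_R", "Frontal_Inf_Tri_R", "Parietal_Sup_R"],
  "executive_control": ["Frontal_Sup_L", "Frontal_Sup_R",
                        "Cingulum_Ant_L", "Cingulum_Ant_R",
                        "Frontal_Mid_Orb_L", "Frontal_Mid_Orb_R"],
  "sensorimotor": ["Precentral_L", "Precentral_R",
                   "Postcentral_L", "Postcentral_R",
                   "Supp_Motor_Area_L", "Supp_Motor_Area_R"],
  "temporo_parietal": ["Frontal_Inf_Oper_L", "Frontal_Inf_Oper_R",
                       "Temporal_Sup_L", "Temporal_Sup_R",
                       "Temporal_Mid_L", "Temporal_Mid_R",
                       "SupraMarginal_L", "SupraMarginal_R"],
  "visual": ["Calcarine_L", "Calcarine_R", "Cuneus_L", "Cuneus_R",
             "Lingual_L", "Lingual_R", "Occipital_Sup_L", "Occipital_Sup_R",
             "Occipital_Mid_L", "Occipital_Mid_R"]
}
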