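roi_label,x,y,z
Precentral_L,-18,-4,49
Precentral_R,18,-4,49
Frontal_Sup_L,-18,41,29
Frontal_Sup_R,18,41,29
Frontal_Sup_Orb_L,-24,43,35
Frontal_Sup_Orb_R,24,43,35
Frontal_Mid_L,-30,45,41
Frontal_Mid_R,30,45,41
Frontal_Mid_Orb_L,-36,41,47
Frontal_Mid_Orb_R,36,41,47
Frontal_Inf_Oper_L,-42,43,29
Frontal_Inf_Oper_R,42,43,29
Frontal_Inf_Tri_L,-18,53,35
Frontal_Inf_Tri_R,18,53,35
Frontal_Inf_Orb_L,-24,49,41
Frontal_Inf_Orb_R,24,49,41
Rolandic_Oper_L,-24,-2,55
Rolandic_Oper_R,24,-2,55
Supp_Motor_Area_L,-30,0,61
Supp_Motor_Area_R,30,0,61
Olfactory_L,-30,51,47
Olfactory_R,30,51,47
Frontal_Sup_Medial_L,-36,53,29
Frontal_Sup_Medial_R,36,53,29
Frontal_Med_Orb_L,-42,49,35
Frontal_Med_Orb_R,42,49,35
Rectus_L,-18,59,41
Rectus_R,18,59,41
Insula_L,-18,-9,-1
Insula_R,18,-9,-1
Cingulum_Ant_L,-24,-7,5
Cingulum_Ant_R,24,-7,5
Cingulum_Mid_L,-30,-5,11
Cingulum_Mid_R,30,-5,11
Cingulum_Post_L,-36,-9,17
Cingulum_Post_R,36,-9,17
Hippocampus_L,-42,-7,-1
Hippocampus_R,42,-7,-1
ParaHippocampal_L,-18,3,5
ParaHippocampal_R,18,3,5
Amygdala_L,-24,-1,11
Amygdala_R,24,-1,11
Calcarine_L,-18,-84,4
Calcarine_R,18,-84,4
Cuneus_L,-24,-82,10
Cuneus_R,24,-82,10
Lingual_L,-30,-80,16
Lingual_R,30,-80,16
Occipital_Sup_L,-36,-84,22
Occipital_Sup_R,36,-84,22
Occipital_Mid_L,-42,-82,4
Occipital_Mid_R,42,-82,4
Occipital_Inf_L,-18,-72,10
Occipital_Inf_R,18,-72,10
Fusiform_L,-18,-29,-21
Fusiform_R,18,-29,-21
Postcentral_L,-18,-54,49
Postcentral_R,18,-54,49
Parietal_Sup_L,-24,-52,55
Parietal_Sup_R,24,-52,55
Parietal_Inf_L,-30,-50,61
Parietal_Inf_R,30,-50,61
SupraMarginal_L,-36,-54,67
SupraMarginal_R,36,-54,67
Angular_L,-42,-52,49
Angular_R,42,-52,49
Precuneus_L,-18,-42,55
Precuneus_R,18,-42,55
Paracentral_Lobule_L,-36,-4,67
Paracentral_Lobule_R,36,-4,67
Caudate_L,-30,1,17
Caudate_R,30,1,17
Putamen_L,-36,3,-1
Putamen_R,36,3,-1
Pallidum_L,-42,-1,5
Pallidum_R,42,-1,5
Thalamus_L,-18,9,11
Thalamus_R,18,9,11
Heschl_L,-24,-27,-15
Heschl_R,24,-27,-15
Temporal_Sup_L,-30,-25,-9
Temporal_Sup_R,30,-25,-9
Temporal_Pole_Sup_L,-36,-29,-3
Temporal_Pole_Sup_R,36,-29,-3
Temporal_Mid_L,-42,-27,-21
Temporal_Mid_R,42,-27,-21
Temporal_Pole_Mid_L,-18,-17,-15
Temporal_Pole_Mid_R,18,-17,-15
Temporal_Inf_L,-24,-21,-9
Temporal_Inf_R,24,-21,-9
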