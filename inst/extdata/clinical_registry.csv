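candidate_id,name,indications,product_type,archetype,phase,last_activity_year,approved_for_indication,recommended_or_routine_use,recommended_for_subgroup_only,inactive_negative_outcome,targets_symptom_only,inferior_to_current,trial_settings,requires_cold_chain,on_who_eml,preclinical_subclass,evidence_concerns
cl-01,Probiotic lactobacilli,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,HIC,no,false,,
cl-02,Vitamin D,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-03,Omega-3 fatty acids,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-04,l-Arginine,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-05,Coenzyme Q10,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,LMIC,no,false,,
cl-06,Dalteparin,prevention,biological,repurposed,III,2021,false,false,false,false,false,false,HIC,yes,true,,
cl-07,Esomeprazole,prevention;treatment,drug,repurposed,III,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-08,Pravastatin,prevention;treatment,drug,repurposed,III,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-09,Selenium,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-10,Vitamin B12,prevention,dietary,repurposed,III,2021,false,false,false,false,false,false,LMIC,no,false,,
cl-11,Chloroquine/hydroxychloroquine,prevention,drug,repurposed,II,2021,false,false,false,false,false,false,HIC,no,true,,
cl-12,l-Citrulline,prevention,dietary,repurposed,II,2021,false,false,false,false,false,false,LMIC,no,false,,
cl-13,Dydrogesterone,prevention,drug,repurposed,II,2021,false,false,false,false,false,false,,unknown,false,,
cl-14,Metformin,prevention;treatment,drug,repurposed,II,2021,false,false,false,false,false,false,HIC;LMIC,no,true,,
cl-15,Ozagrel,prevention;treatment,drug,repurposed,II,2021,false,false,false,false,false,false,HIC,unknown,false,,
cl-16,Pentaerythrityl tetranitrate,prevention,drug,repurposed,I,2021,false,false,false,false,false,false,HIC,no,false,,
cl-17,Salsalate,prevention,drug,repurposed,I,2021,false,false,false,false,false,false,HIC,no,false,,
cl-18,Sulforaphane,treatment,dietary,repurposed,III,2021,false,false,false,false,false,false,HIC,no,false,,
cl-19,Resveratrol,treatment,dietary,repurposed,III,2021,false,false,false,false,false,false,LMIC,no,false,,
cl-20,Curcuma longa,treatment,dietary,repurposed,II,2021,false,false,false,false,false,false,LMIC,no,false,,
cl-21,Vitamin B3,treatment,dietary,repurposed,II,2021,false,false,false,false,false,false,HIC,no,false,,
cl-22,Serelaxin,treatment,biological,new,II,2021,false,false,false,false,false,false,HIC,yes,false,,
cl-23,Sildenafil citrate,treatment,drug,repurposed,II,2021,false,false,false,false,false,false,HIC;LMIC,no,false,,
cl-24,Tadalafil,treatment,drug,repurposed,II,2021,false,false,false,false,false,false,HIC,no,false,,
cl-25,Rosuvastatin,treatment,drug,repurposed,II,2021,false,false,false,false,false,false,LMIC,no,false,,
cl-26,Iloprost,treatment,drug,repurposed,II,2021,false,false,false,false,false,false,HIC,unknown,false,,
cl-27,Vardenafil,treatment,drug,repurposed,I,2021,false,false,false,false,false,false,HIC,no,false,,
cl-28,Purnica granatum extract,treatment,dietary,repurposed,I,2021,false,false,false,false,false,false,HIC,no,false,,
cl-29,Sulfasalazine,treatment,drug,repurposed,I,2021,false,false,false,false,false,false,HIC,no,true,,
cl-30,Conestat alfa,treatment,biological,repurposed,I,2021,false,false,false,false,false,false,HIC,yes,false,,
cl-31,S-nitrosoglutathione,treatment,drug,new,I,2021,false,false,false,false,false,false,HIC,unknown,false,,
cl-32,RMC 035,treatment,biological,new,I,2021,false,false,false,false,false,false,HIC,yes,false,,
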