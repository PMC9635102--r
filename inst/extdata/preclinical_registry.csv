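candidate_id,name,indications,product_type,archetype,phase,last_activity_year,approved_for_indication,recommended_or_routine_use,recommended_for_subgroup_only,inactive_negative_outcome,targets_symptom_only,inferior_to_current,trial_settings,requires_cold_chain,on_who_eml,preclinical_subclass,evidence_concerns
pc-01,l-Ergothione,prevention,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-02,Hydrogen-rich saline,prevention,drug,repurposed,preclinical,2017,false,false,false,false,false,false,,unknown,false,antioxidant,
pc-03,Simvastatin,prevention,drug,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,enzyme inhibitors (statins),
pc-04,MZe786,prevention,drug,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,hydrogen sulphide donors,
pc-05,Grape seed extract,prevention,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-06,Mangiferin,prevention,dietary,repurposed,preclinical,2017,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-07,Scutellaria baicalensis root extract,prevention,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-08,Uncaria rhynchophylla extract,prevention,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-09,Vitexin,prevention,dietary,repurposed,preclinical,2017,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-10,Vitis labrusca/vinifera extract,prevention,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-11,TRV027,prevention,drug,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,small molecule,
pc-12,Lovastatin,prevention;treatment,drug,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,enzyme inhibitors (statins),
pc-13,AP39,prevention;treatment,drug,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,hydrogen sulphide donors,
pc-14,Trehalose,prevention;treatment,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,macronutrients,
pc-15,Quercetin,prevention;treatment,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,polyphenol,
pc-16,Ad-VEGF [viral vector delivery],prevention;treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,DNA/siRNA/mRNA,
pc-17,Cibinetide,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-18,Etanercept,treatment,biological,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-19,Liraglutide,treatment,biological,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-20,Placental growth factor,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-21,SynB1-ELP-p50i [polypeptide delivery],treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-22,VEGF-B [polypeptide delivery],treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,amino acid-peptide,
pc-23,Ferulic acid,treatment,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,antioxidant,
pc-24,HTHQ,treatment,drug,new,preclinical,2017,false,false,false,false,false,false,,unknown,false,antioxidant,
pc-25,MitoQ,treatment,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,antioxidant,
pc-26,Emiplacel,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,cell therapy,
pc-27,Haemoglobin-vesicles [nanoparticle delivery],treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,cell therapy,
pc-28,Regulatory T cells,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,cell therapy,
pc-29,Euterpe oleracea,treatment,dietary,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,herbal,
pc-30,Toki-shakuyaku-san,treatment,dietary,repurposed,preclinical,2017,false,false,false,false,false,false,,unknown,false,herbal,
pc-31,GYY4137,treatment,drug,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,hydrogen sulphide donors,
pc-32,AGT-targeting siRNA,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,DNA/siRNA/mRNA,
pc-33,GPCR-AAB binding aptamers,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,DNA/siRNA/mRNA,
pc-34,sFlt-1-targeting siRNA,treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,DNA/siRNA/mRNA,
pc-35,sFlt-1-targeting siRNA [nanoparticle delivery],treatment,biological,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,DNA/siRNA/mRNA,
pc-36,Gefitinib,treatment,drug,repurposed,preclinical,2020,false,false,false,false,false,false,,unknown,false,small molecule,
pc-37,SB203580,treatment,drug,new,preclinical,2020,false,false,false,false,false,false,,unknown,false,small molecule,
pc-38,Sofalcone,treatment,drug,repurposed,preclinical,2017,false,false,false,false,false,false,,unknown,false,small molecule,
pc-39,Carveol,treatment,drug,new,preclinical,2017,false,false,false,false,false,false,,unknown,false,vascular agents,
pc-40,Tetramethylpyrazine,treatment,drug,repurposed,preclinical,2017,false,false,false,false,false,false,,unknown,false,vascular agents,
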