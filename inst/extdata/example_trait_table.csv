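taxon_id,taxon_name,rank,parent_genus,group,n_fixation,mixotrophy,motility,buoyancy,harmful,excluded_category,override_note
sp_dolichospermum,Dolichospermum lemmermannii,species,Dolichospermum,cyanobacteria,1,0,0,1,1,,
gen_aphanizomenon,Aphanizomenon,genus,,cyanobacteria,1,0,0,1,0,,harmful=1 # A. flosaquae listed as harmful
gen_anabaena,Anabaena,genus,,cyanobacteria,1,0,0,1,0,,harmful=1 # pelagic Dolichospermum records under the old name
gen_snowella,Snowella,genus,,cyanobacteria,0,0,0,0,0,,buoyancy=0 # majority of local species lack gas vesicles
sp_snowella1,Snowella lacustris,species,Snowella,cyanobacteria,0,0,0,1,0,,
sp_snowella2,Snowella litoralis,species,Snowella,cyanobacteria,0,0,0,0,0,,
gen_amphidinium,Amphidinium,genus,,eukaryote,0,1,1,0,0,,harmful=0 # majority of local species non-toxic
sp_amphidinium1,Amphidinium crassum,species,Amphidinium,eukaryote,0,1,1,0,1,,
ord_prymnesiales,Prymnesiales,order,,eukaryote,0,1,1,0,0,,harmful=1 # several toxic species in the order
gen_chrysochromulina,Chrysochromulina,genus,,eukaryote,0,1,1,0,1,,
sp_skeletonema,Skeletonema marinoi,species,Skeletonema,eukaryote,0,0,0,0,0,,
sp_ebria,Ebria tripartita,species,Ebria,eukaryote,0,0,1,0,0,heterotroph,
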