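pzn,brand_name,active_ingredients,form_class,device_subtype,prescription_only,strengths_mg,divisible,orodispersible,extended_release,palatability_issue,requires_technique_training,self_measurement_linked,equivalence_group
10000001,AeroMist,salbutamol,inhaler,metered_dose_inhaler,true,0.1,false,false,false,false,false,false,salbutamol_inh
10000002,ElpenAir,formoterol,inhaler,elpenhaler,true,0.012,false,false,false,false,false,false,formoterol_inh
10000003,NebuFlow,ipratropium,inhaler,nebuliser,true,0.25,false,false,false,false,false,false,ipratropium_inh
10000004,CapsInhal,tiotropium,inhaler,capsule_inhaler,true,0.018,false,false,false,false,false,false,tiotropium_inh
10000005,BreezAir,indacaterol,inhaler,other_inhaler,true,0.15,false,false,false,false,false,false,indacaterol_inh
10000011,InsuVial,insulin glargine,injection,non_prefilled_injector,true,100,false,false,false,false,false,false,insulin_glargine
10000012,InsuPen,insulin glargine,injection,prefilled_injector,true,100,false,false,false,false,false,false,insulin_glargine
10000013,EnoxaPen,enoxaparin,injection,prefilled_injector,true,40,false,false,false,false,false,false,enoxaparin
10000021,DoloPatch,fentanyl,transdermal_patch,,true,0.075,false,false,false,false,false,false,fentanyl_td
10000022,NasoSpray,mometasone,nasal,,true,0.05,false,false,false,false,false,false,mometasone_nasal
10000023,NasoFree,xylometazoline,nasal,,false,0.1,false,false,false,false,false,false,xylometazoline_nasal
10000024,BuccoTab,miconazole,oropharyngeal_solid,,true,50,false,false,false,false,false,false,miconazole_oroph
10000025,OroRinse,chlorhexidine,oropharyngeal_liquid,,true,200,false,false,false,false,false,false,chlorhexidine_oroph
10000026,OcuDrop,latanoprost,ophthalmic,eye_drops,true,0.005,false,false,false,false,false,false,latanoprost_eye
10000027,OcuGel,dexpanthenol,ophthalmic,eye_ointment,false,250,false,false,false,false,false,false,dexpanthenol_eye
10000028,RectoSupp,mesalazine,rectal,,true,500,false,false,false,false,false,false,mesalazine_rect
10000029,DermaCort,clobetasol,dermatological,,true,0.5,false,false,false,false,false,false,clobetasol_derm
10000030,DermaSoft,urea,dermatological,,false,100,false,false,false,false,false,false,urea_derm
10000031,PediSyrup,cefalexin,liquid_oral,liquid_measuring_device,true,250,false,false,false,false,false,false,cefalexin_liq
10000032,DrySyr,amoxicillin,liquid_oral,dry_syrup,true,250,false,false,false,false,false,false,amoxicillin_liq
10000033,GuttaDol,metamizole,liquid_oral,oral_drops,true,500,false,false,false,false,false,false,metamizole_liq
10000034,BitterSol,prednisolone,liquid_oral,liquid_measuring_device,true,10,false,false,false,true,false,false,prednisolone_liq
10000035,OtoDrop,ofloxacin,otological,,true,3,false,false,false,false,false,false,ofloxacin_oto
10000036,GynoVag,clotrimazole,vaginal,,false,200,false,false,false,false,false,false,clotrimazole_vag
10000037,TechTab,alendronate,solid_oral,,true,70,false,false,false,false,true,false,alendronate
10000038,CoagTab,phenprocoumon,solid_oral,,true,3,true,false,false,false,false,true,phenprocoumon
10000039,FlexGel,glucosamine,other,,false,1500,false,false,false,false,false,false,glucosamine
04773414,ThyroTab,levothyroxine,solid_oral,,true,0.1,true,false,false,false,false,false,levothyroxine
20000002,GastroProt,pantoprazole,solid_oral,,true,40,false,false,false,false,false,false,pantoprazole
20000003,LipoStat,atorvastatin,solid_oral,,true,20,true,false,false,false,false,false,atorvastatin
20000004,UricNorm,allopurinol,solid_oral,,true,300,true,false,false,false,false,false,allopurinol
20000005,CandeSar,candesartan,solid_oral,,true,8,true,false,false,false,false,false,candesartan
20000006,SeroLift,sertraline,solid_oral,,true,50,true,false,false,false,false,false,sertraline
20000007,MemoCare,donepezil,solid_oral,,true,10,true,false,false,false,false,false,donepezil
20000008,VitaSun,colecalciferol,solid_oral,,false,0.025,false,false,false,false,false,false,colecalciferol
20000009,AllerStop,cetirizine,solid_oral,,false,10,true,false,false,false,false,false,cetirizine
20000010,AquaTor,torasemide,solid_oral,,true,10,true,false,false,false,false,false,torasemide
30000001,AmloTab 5,amlodipine,solid_oral,,true,5,true,false,false,false,false,false,amlodipine
30000002,AmloTab 10,amlodipine,solid_oral,,true,10,true,false,false,false,false,false,amlodipine
30000003,GabaTab 300,gabapentin,solid_oral,,true,300,false,false,false,false,false,false,gabapentin
30000004,GabaTab 600,gabapentin,solid_oral,,true,600,true,false,false,false,false,false,gabapentin
30000005,RispTab 2,risperidone,solid_oral,,true,2,true,false,false,false,false,false,risperidone
30000006,RispSol 2,risperidone,liquid_oral,liquid_measuring_device,true,2,false,false,false,false,false,false,risperidone
30000007,RispOro 2,risperidone,solid_oral,,true,2,false,true,false,false,false,false,risperidone
30000008,MetoTab 50,metoprolol,solid_oral,,true,50,true,false,false,false,false,false,metoprolol
30000009,MetoRet 150,metoprolol,solid_oral,,true,150,false,false,true,false,false,false,metoprolol
30000010,RamiTab 5,ramipril,solid_oral,,true,5,true,false,false,false,false,false,ramipril
30000011,HctTab 12.5,hydrochlorothiazide,solid_oral,,true,12.5,true,false,false,false,false,false,hydrochlorothiazide
30000012,RamiComp 5/12.5,ramipril+hydrochlorothiazide,solid_oral,,true,5+12.5,false,false,false,false,false,false,ramipril_hct
30000013,IbuTab 400,ibuprofen,solid_oral,,false,400,true,false,false,false,false,false,ibuprofen
30000014,IbuTab 600,ibuprofen,solid_oral,,true,600,true,false,false,false,false,false,ibuprofen
20000011,PressoNorm,lisinopril,solid_oral,,true,10,true,false,false,false,false,false,lisinopril
20000012,TensioBlock,losartan,solid_oral,,true,50,true,false,false,false,false,false,losartan
20000013,GlucoMet,metformin,solid_oral,,true,850,false,false,false,false,false,false,metformin
20000014,GlipCare,sitagliptin,solid_oral,,true,100,false,false,false,false,false,false,sitagliptin
20000015,EmpaGlif,empagliflozin,solid_oral,,true,10,false,false,false,false,false,false,empagliflozin
20000016,RosuStat,rosuvastatin,solid_oral,,true,10,true,false,false,false,false,false,rosuvastatin
20000017,EzeLip,ezetimibe,solid_oral,,true,10,false,false,false,false,false,false,ezetimibe
20000018,ClopiCard,clopidogrel,solid_oral,,true,75,false,false,false,false,false,false,clopidogrel
20000019,ApixaDol,apixaban,solid_oral,,true,5,false,false,false,false,false,false,apixaban
20000020,EscitaLift,escitalopram,solid_oral,,true,10,true,false,false,false,false,false,escitalopram
20000021,MirtaCalm,mirtazapine,solid_oral,,true,30,true,false,false,false,false,false,mirtazapine
20000022,QuetiNight,quetiapine,solid_oral,,true,25,false,false,false,false,false,false,quetiapine
20000023,LevetiTab,levetiracetam,solid_oral,,true,500,true,false,false,false,false,false,levetiracetam
20000024,PregaCalm,pregabalin,solid_oral,,true,75,false,false,false,false,false,false,pregabalin
20000025,TamsuFlow,tamsulosin,solid_oral,,true,0.4,false,false,false,false,false,false,tamsulosin
20000026,FinaCare,finasteride,solid_oral,,true,5,false,false,false,false,false,false,finasteride
20000027,HydroxCalm,hydroxyzine,solid_oral,,true,25,true,false,false,false,false,false,hydroxyzine
20000028,LoraStop,loratadine,solid_oral,,false,10,false,false,false,false,false,false,loratadine
20000029,FamoGast,famotidine,solid_oral,,true,40,false,false,false,false,false,false,famotidine
20000030,UrsoLiv,ursodeoxycholic acid,solid_oral,,true,250,false,false,false,false,false,false,ursodeoxycholic
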