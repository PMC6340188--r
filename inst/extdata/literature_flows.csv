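species,method,vessel,mean_flow_ml_min_kg,pct_cvo,n_measurements,standard_error
human,2D PC CMR,CVO,465,NA,NA,NA
human,2D PC CMR,MPA,261,56,NA,NA
human,2D PC CMR,AAo,191,41,NA,NA
human,2D PC CMR,SVC,137,29,NA,NA
human,2D PC CMR,DA,187,40,NA,NA
human,2D PC CMR,PBF,74,15,NA,NA
human,2D PC CMR,DAo,252,54,NA,NA
human,2D PC CMR,UV,134,29,NA,NA
human,2D PC CMR,FO,135,29,NA,NA
mouse,ultrasound,CVO,1020,NA,NA,NA
mouse,ultrasound,MPA,550,52,NA,NA
mouse,ultrasound,AAo,470,48,NA,NA
mouse,ultrasound,SVC,210,23,NA,NA
mouse,ultrasound,DA,340,36,NA,NA
mouse,ultrasound,PBF,210,21,NA,NA
mouse,ultrasound,DAo,410,42,NA,NA
mouse,ultrasound,UV,130,14,NA,NA
mouse,ultrasound,FO,270,31,NA,NA
mouse,ultrasound,IVCp,290,30,NA,NA
mouse,ultrasound,DV,90,10,NA,NA
sheep,microspheres,CVO,450,NA,NA,NA
sheep,microspheres,MPA,300,67,NA,NA
sheep,microspheres,AAo,137,30,NA,NA
sheep,microspheres,SVC,108,24,NA,NA
sheep,microspheres,DA,260,58,NA,NA
sheep,microspheres,PBF,36,8,NA,NA
sheep,microspheres,DAo,305,68,NA,NA
sheep,microspheres,UV,180,40,NA,NA
sheep,microspheres,FO,115,26,NA,NA
sheep,microspheres,IVCd,125,28,NA,NA
sheep,microspheres,IVCp,305,68,NA,NA
sheep,microspheres,DV,100,22,NA,NA
sheep,2D PC CMR,CVO,517,NA,NA,NA
sheep,2D PC CMR,MPA,266,51,NA,NA
sheep,2D PC CMR,AAo,236,46,NA,NA
sheep,2D PC CMR,SVC,121,23,NA,NA
sheep,2D PC CMR,DA,200,39,NA,NA
sheep,2D PC CMR,PBF,89,17,NA,NA
sheep,2D PC CMR,DAo,352,68,NA,NA
sheep,2D PC CMR,UV,213,41,NA,NA
sheep,2D PC CMR,FO,164,32,NA,NA
sheep,2D PC CMR,DV,105,20,NA,NA
sheep,4D flow CMR,CVO,546,NA,NA,NA
sheep,4D flow CMR,MPA,284,52,6,35.6
sheep,4D flow CMR,AAo,245,45,5,30.4
sheep,4D flow CMR,SVC,181,33,4,20.4
sheep,4D flow CMR,DA,265,48,5,13.5
sheep,4D flow CMR,PBF,38,7,3,2.3
sheep,4D flow CMR,DAo,333,61,10,31.2
sheep,4D flow CMR,UV,197,36,8,20.2
sheep,4D flow CMR,FO,174,32,5,35.3
sheep,4D flow CMR,IVCd,117,21,6,10.2
sheep,4D flow CMR,IVCp,357,65,8,27.1
sheep,4D flow CMR,DV,144,26,7,22.1
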