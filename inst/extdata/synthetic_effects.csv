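"record_id","meta_id","es_value","es_metric","ci_lower","ci_upper","n_treatment","n_control","year","vessel_bed","modality","bio_category","is_duplicate"
"E0001","M002",0.265,"cohens_d",-0.2549,0.785,38,23,2003,"macro","plethysmography","pathophysiology",FALSE
"E0002","M006",-0.4944,"cohens_d",-1.1968,0.208,29,11,1992,"macro","ultrasound","exercise",FALSE
"E0003","M003",0.1959,"cohens_d",-0.4886,0.8805,20,14,2012,"micro","plethysmography","exercise",FALSE
"E0004","M006",0.4585,"hedges_g",-0.2945,1.2114,15,13,2021,"micro","ultrasound","pathophysiology",TRUE
"E0005","M002",0.5114,"cohens_d",-0.0404,1.0633,23,30,2014,"macro","ultrasound","exercise",FALSE
"E0006","M005",0.2722,"cohens_d",-0.4364,0.9808,13,19,2001,"macro","ultrasound","pathophysiology",FALSE
"E0007","M005",0.3486,"hedges_g",-0.2494,0.9466,20,24,2003,"macro","other","supplement_diet",FALSE
"E0008","M002",0.5224,"cohens_d",-0.1946,1.2393,13,19,2021,"macro","ultrasound","supplement_diet",FALSE
"E0009","M005",-0.4946,"cohens_d",-1.2651,0.2758,15,12,1997,"micro","ultrasound","exercise",FALSE
"E0010","M001",-1.619,"hedges_g",-2.2472,-0.9908,45,17,2008,"macro","ultrasound","supplement_diet",FALSE
"E0011","M004",2.0891,"hedges_g",1.2809,2.8974,15,23,1992,"macro","ultrasound","exercise",FALSE
"E0012","M005",0.2675,"cohens_d",-0.337,0.872,19,24,2005,"micro","ultrasound","pathophysiology",FALSE
"E0013","M005",-0.3609,"cohens_d",-0.9535,0.2317,18,29,2019,"macro","ultrasound","other",FALSE
"E0014","M005",-0.3343,"cohens_d",-0.977,0.3084,34,13,2014,"macro","ultrasound","supplement_diet",FALSE
"E0015","M006",0.8465,"hedges_g",0.1253,1.5677,12,24,2019,"macro","other","supplement_diet",FALSE
"E0016","M002",0.9899,"cohens_d",0.2498,1.7301,26,11,2014,"macro","ultrasound","pathophysiology",FALSE
"E0017","M002",0.7696,"cohens_d",0.1966,1.3426,66,15,2009,"macro","ultrasound","supplement_diet",FALSE
"E0018","M002",0.3437,"hedges_g",-0.6066,1.2941,30,5,2014,"micro","ultrasound","pathophysiology",FALSE
"E0019","M005",0.2282,"cohens_d",-0.3228,0.7793,20,35,2020,"macro","ultrasound","pathophysiology",FALSE
"E0020","M006",0.4585,"hedges_g",-0.2945,1.2114,15,13,2021,"micro","ultrasound","pathophysiology",FALSE
"E0021","M006",9.0747,"cohens_d",,,50,10,2009,"unknown","unknown","unknown",FALSE
"E0022","M002",1.1012,"cohens_d",0.4726,1.7297,27,19,2011,"macro","ultrasound","pathophysiology",FALSE
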