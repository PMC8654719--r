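"meta_id","summary_es","ci_lower","ci_upper"
"M001",-0.6181,-0.7946,-0.4416
"M002",-0.285,-0.6446,0.0746
"M003",0.4065,0.1656,0.6474
"M004",-0.9428,-1.3351,-0.5505
"M005",0.4497,-0.2698,1.1693
"M006",0.1054,-0.4065,0.6173
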