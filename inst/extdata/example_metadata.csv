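sample_id,brand,batch_id,quality_class,component,sapi_percent
DemoBrand-QA01-001,DemoBrand,DemoBrand-QA01,quality_assured,artesunate,100.489910183
DemoBrand-QA01-002,DemoBrand,DemoBrand-QA01,quality_assured,artesunate,95.1494314447
DemoBrand-QA02-003,DemoBrand,DemoBrand-QA02,quality_assured,artesunate,104.105457392
DemoBrand-QA02-004,DemoBrand,DemoBrand-QA02,quality_assured,artesunate,94.6065576491
DemoBrand-FK01-001,DemoBrand,DemoBrand-FK01,falsified,artesunate,0
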