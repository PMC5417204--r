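{"grid":[740,748,756,764,772,780,788,796,804,812,820,828,836,844,852,860,868,876,884,892,900,908,916,924,932,940,948,956,964,972,980,988,996,1004,1012,1020,1028,1036,1044,1052,1060],"projection":[[0.324310782637448,0.238876526406726,0.153442270176034,0.068008013945337,-0.0174262422853647,-0.102860498516066,-0.0701228261300098,0.0307382395947223,0.122277060407847,0.172846394131712,0.180086517202704,0.145854190319056,0.0718131350282073,-0.0360691593055598,-0.144288204527072,-0.174670331817892,-0.110438899706338,-0.0623966748398405,-0.0910015353777396,-0.113744676533608,-0.0519026518880253,0.0528569148693541,0.138611992468682,0.185136785628292,0.189870859063754,0.153353891921696,0.0728530952317015,-0.0581823797237064,-0.209168071754052,-0.254321235493047,-0.14452121478599,-0.00263704079604978,0.09451525401331,0.149194452646538,0.167661510965305,0.149902149020255,0.0428994840770043,-0.0641031808662489,-0.171105845809493,-0.278108510752732,-0.385111175696002]],"center":[-0.00101283125083337,-0.000746068713735705,-0.000479306176638145,-0.000212543639540563,5.42188975570329e-05,0.000320981434654626,0.000219033549620674,-9.6125130705302e-05,-0.000381890146007025,-0.000539895622291398,-0.000562234554255149,-0.000455199740543595,-0.000224132380956886,0.000113123554982269,0.000451310768660243,0.000546270290486684,0.000345019154978867,0.000194386050678783,0.000283533706014836,0.000354381047924034,0.000161601928630449,-0.000165304019385304,-0.000432673991167775,-0.000577399480360923,-0.000592464919494605,-0.000478392036153663,-0.000228117653715801,0.00018110606068286,0.000652610763701838,0.000793799294844645,0.000451348515380065,8.52843068423202e-06,-0.000294269120995515,-0.000465412507453537,-0.000524139718233271,-0.000468873451207244,-0.000135978818633555,0.000196915813940139,0.000529810446513807,0.00086270507908746,0.0011955997116612],"mean":1.06726151354042e-19,"covariance":[[2.06492334987582e-08]],"threshold":3.89059188641312,"threshold_quantile":0.9999,"k":1,"variance_kept":0.99,"shrinkage":0.05,"explained":[0.999996796357705,2.71540713033502e-06,4.88235165083802e-07,9.48964999621071e-31],"manifest":{"sample_id":["DemoBrand-QA01-001","DemoBrand-QA01-002","DemoBrand-QA02-003","DemoBrand-QA02-004"],"batch_id":["DemoBrand-QA01","DemoBrand-QA01","DemoBrand-QA02","DemoBrand-QA02"]},"schema":"nirscreen/class_model/1"}
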