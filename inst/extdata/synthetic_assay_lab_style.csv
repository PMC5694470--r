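Drug,hERG_IC50_uM,hERG_hill,CaV_IC50_uM,NaL_IC50_nM,EFTPC_uM,CM_category,TdP_label_warning,trapping_ratio
SYN001,45.62723737033287,1.55,8358.763041584632,62814.02297829998,27.73838715627413,CM1,TRUE,0.676
SYN002,56.014653418610486,1,337.4522031271538,187525.50718821588,0.7371328654035476,CM3,FALSE,0.983
SYN003,0.13949483873411223,1.17,0.01942999503374904,986.0222957155984,0.005423125069321445,CM3,FALSE,0.76
SYN004,20.979276375007103,1.55,16.19078648803197,129933.90297813507,0.006492997632741092,CM3,FALSE,0.566
SYN005,3.6896237024884018,1.58,7.0245334677549875,19166.848591892223,0.07772374658884323,CM3,FALSE,0.85
SYN006,1.1922952026529101,0.89,2.222167985576407,2912.2293136788085,8.515734324772511e-4,CM3,FALSE,0.189
SYN007,8.837984968074748,1.18,334.3389356951472,627650.6549935265,0.013970137094400956,CM3,FALSE,0.271
SYN008,0.034567374036586926,1.25,0.0012461669448036827,79.89223551936,2.7247008744406504e-5,CM3,FALSE,0.828
SYN009,4.245894136209076,1.52,6.654454733364132,10827.331073361804,0.15537657461089857,CM3,FALSE,0.693
SYN010,6.610877902136491,0.91,0.4382281701803373,110217.36633314559,0.018753705709849855,CM3,FALSE,0.241
SYN011,0.6775901825803777,1.59,0.10560170885831043,5823.808511143371,0.843185189046237,CM3,FALSE,0.043
SYN012,7.524003806768491,1.56,5.153444455125023,28178.264935342853,0.004546358699710179,CM3,FALSE,0.14
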