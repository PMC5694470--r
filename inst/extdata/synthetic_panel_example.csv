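name,ic50_IKr,ic50_ICaV,ic50_INaL,ic50_INa_fast,ic50_IKs,ic50_IK1,ic50_Ito,hill_IKr,hill_ICaV,hill_INaL,hill_INa_fast,hill_IKs,hill_IK1,hill_Ito,eftpc,redfern,crediblemeds,champeroux,cipa,label_warning,trapping
SYN001,45627.23737033287,8358763.041584632,62814.02297829998,,,,,1.55,1,1,,,,,27738.38715627413,,CM1,,,TRUE,0.676
SYN002,56014.653418610484,337452.2031271538,187525.50718821588,,,,,1,1,1,,,,,737.1328654035476,,CM3,,,FALSE,0.983
SYN003,139.49483873411222,19.42999503374904,986.0222957155984,,,,,1.17,1,1,,,,,5.423125069321445,,CM3,,,FALSE,0.76
SYN004,20979.276375007103,16190.786488031972,129933.90297813507,,,,,1.55,1,1,,,,,6.492997632741091,,CM3,,,FALSE,0.566
SYN005,3689.6237024884017,7024.533467754987,19166.848591892223,,,,,1.58,1,1,,,,,77.72374658884324,,CM3,,,FALSE,0.85
SYN006,1192.2952026529101,2222.167985576407,2912.2293136788085,,,,,0.89,1,1,,,,,0.851573432477251,,CM3,,,FALSE,0.189
SYN007,8837.984968074748,334338.9356951472,627650.6549935265,,,,,1.18,1,1,,,,,13.970137094400956,,CM3,,,FALSE,0.271
SYN008,34.567374036586926,1.2461669448036827,79.89223551936,,,,,1.25,1,1,,,,,0.027247008744406505,,CM3,,,FALSE,0.828
SYN009,4245.894136209075,6654.454733364132,10827.331073361804,,,,,1.52,1,1,,,,,155.37657461089856,,CM3,,,FALSE,0.693
SYN010,6610.877902136491,438.22817018033726,110217.36633314559,,,,,0.91,1,1,,,,,18.753705709849854,,CM3,,,FALSE,0.241
SYN011,677.5901825803777,105.60170885831043,5823.808511143371,,,,,1.59,1,1,,,,,843.1851890462369,,CM3,,,FALSE,0.043
SYN012,7524.003806768491,5153.4444551250235,28178.264935342853,,,,,1.56,1,1,,,,,4.546358699710179,,CM3,,,FALSE,0.14
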