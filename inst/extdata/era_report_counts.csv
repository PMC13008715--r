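drug,variable,category,n
bosentan,total,reports,35112
bosentan,sex,F,17211
bosentan,sex,M,6221
bosentan,sex,Unknown,11680
bosentan,age_band,<18,2252
bosentan,age_band,18-65,9043
bosentan,age_band,>=65,10423
bosentan,age_band,Unknown,13394
bosentan,outcome,HO,17666
bosentan,outcome,DE,13688
bosentan,outcome,OT,6840
bosentan,outcome,LT,936
bosentan,outcome,DS,439
bosentan,outcome,RI,331
bosentan,outcome,CA,19
ambrisentan,total,reports,48411
ambrisentan,sex,F,35958
ambrisentan,sex,M,11786
ambrisentan,sex,Unknown,667
ambrisentan,age_band,<18,1087
ambrisentan,age_band,18-65,18430
ambrisentan,age_band,>=65,16268
ambrisentan,age_band,Unknown,12626
ambrisentan,outcome,HO,21670
ambrisentan,outcome,DE,7631
ambrisentan,outcome,OT,17748
ambrisentan,outcome,LT,460
ambrisentan,outcome,DS,341
ambrisentan,outcome,RI,59
ambrisentan,outcome,CA,14
macitentan,total,reports,29877
macitentan,sex,F,21819
macitentan,sex,M,7732
macitentan,sex,Unknown,326
macitentan,age_band,<18,312
macitentan,age_band,18-65,11177
macitentan,age_band,>=65,12279
macitentan,age_band,Unknown,6109
macitentan,outcome,HO,18004
macitentan,outcome,DE,7208
macitentan,outcome,OT,5607
macitentan,outcome,LT,487
macitentan,outcome,DS,417
macitentan,outcome,RI,9
macitentan,outcome,CA,28
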