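id,tier,mass_kda,reference_subunit,evidence
RLS2,intact,52.68,RLS2,0-475
RSS174,intact,15.19,RSS174,MQVWPPIGKK;YETLSYLPDL;SQGFVYRENH;KSPGYYDGRY;WTMWKLPMFG
RSS175,intact,15.11,RSS175,MQVWPPIGKK;YETLSYLPDL;SQGFVYRENH;KSPGYYDGRY;WTMWKLPLFG
dp39,fragment,39.03,RLS2,60-390
dp12,fragment,11.98,RLS2,0-105
dp37,fragment,37.03,RLS2,95-440
dp44,fragment,9.64,,YETLSYLPDL;SQGFVYRENH
dp7,fragment,7.01,RLS2,61-130
dp15,fragment,15.01,RLS2,70-230
dp17,fragment,16.96,RLS2,80-340
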