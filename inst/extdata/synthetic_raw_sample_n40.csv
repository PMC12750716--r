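"maternal_age","infant_age","parity","delivery_mode","education","employment","assets","hiv","hps_high","hsi_high","relationship","x_helpful","bses_total","m_bses_high","y_exclusive","nurse_helpful","bses_1","bses_2","bses_3","bses_4","bses_5","bses_6","bses_7","bses_8","bses_9","bses_10","bses_11","bses_12","bses_13","bses_14","currently_breastfeeding","ever_given_other","hlq_hps_1","hlq_hps_2","hlq_hps_3","hlq_hps_4","hlq_hsi_1","hlq_hsi_2","hlq_hsi_3","hlq_hsi_4","asset_1","asset_2","asset_3","asset_4","asset_5","asset_6","asset_7","asset_8","asset_9","asset_10","asset_11","asset_12","asset_13"
33,3,1,0,1,0,9,0,1,0,"single",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,0,0,0,0
35,4,2,0,1,1,10,0,1,1,"living_with_partner",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,0,0,0
35,2,2,0,1,0,6,1,0,1,"relationship_living_alone",0,70,1,0,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,FALSE,FALSE,2,2,2,2,3,3,3,3,1,1,1,1,1,1,0,0,0,0,0,0,0
26,4,0,1,1,1,8,1,1,1,"single",0,45,0,1,"sometimes",4,4,4,3,3,3,3,3,3,3,3,3,3,3,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
34,8,1,0,0,0,10,0,1,1,"single",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,0,0,0
27,10,1,0,1,0,4,0,1,0,"single",0,64,1,0,"sometimes",5,5,5,5,5,5,5,5,4,4,4,4,4,4,TRUE,TRUE,3,3,3,3,2,2,2,2,1,1,1,1,0,0,0,0,0,0,0,0,0
26,13,3,0,1,0,9,0,1,0,"single",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,0,0,0,0
31,3,1,0,1,1,10,0,1,1,"living_with_partner",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,0,0,0
20,3,0,0,1,0,9,0,1,1,"relationship_living_alone",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,0,0,0,0
32,17,3,1,1,0,8,0,1,1,"married",0,46,0,1,"sometimes",4,4,4,4,3,3,3,3,3,3,3,3,3,3,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
26,4,1,0,1,0,10,0,1,1,"single",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,0,0,0
32,11,0,0,1,1,8,0,1,1,"living_with_partner",1,66,1,1,"always",5,5,5,5,5,5,5,5,5,5,4,4,4,4,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
24,5,1,0,1,0,9,0,0,1,"living_with_partner",0,69,1,0,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,4,FALSE,TRUE,2,2,2,2,3,3,3,3,1,1,1,1,1,1,1,1,1,0,0,0,0
35,4,1,1,1,0,10,0,1,1,"living_with_partner",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,0,0,0
25,10,0,0,0,0,8,0,1,1,"relationship_living_alone",0,63,1,1,"seldom",5,5,5,5,5,5,5,4,4,4,4,4,4,4,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
43,12,1,0,1,0,8,0,0,1,"relationship_living_alone",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,2,2,2,2,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
31,1,2,0,1,0,11,0,1,1,"relationship_living_alone",0,70,1,0,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,TRUE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,1,0,0
22,3,1,1,0,0,9,1,1,0,"single",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,0,0,0,0
29,2,1,0,0,0,9,1,1,0,"relationship_living_alone",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,0,0,0,0
25,5,1,0,1,0,8,0,1,1,"living_with_partner",1,70,1,0,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,FALSE,TRUE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
21,2,0,1,1,0,7,1,1,1,"living_with_partner",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,0,0,0,0,0,0
26,9,0,0,0,0,7,1,1,1,"single",0,70,1,0,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,TRUE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,0,0,0,0,0,0
31,3,0,1,1,1,5,0,1,0,"living_with_partner",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,0,0,0,0,0,0,0,0
18,7,1,0,1,1,10,0,1,1,"single",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,1,0,0,0
25,2,0,0,1,1,8,0,1,1,"relationship_living_alone",0,69,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,4,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
23,3,1,0,0,0,8,1,1,0,"single",0,64,1,1,"sometimes",5,5,5,5,5,5,5,5,4,4,4,4,4,4,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,0,0,0,0,0
40,1,0,0,1,0,6,0,1,1,"living_with_partner",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,0,0,0,0,0,0,0
29,2,2,0,1,0,10,1,1,0,"single",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,1,0,0,0
29,4,2,1,1,1,12,1,1,0,"single",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,1,1,1,0
25,3,1,0,1,0,6,0,0,1,"relationship_living_alone",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,2,2,2,2,3,3,3,3,1,1,1,1,1,1,0,0,0,0,0,0,0
27,4,1,1,1,0,9,0,1,1,"relationship_living_alone",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,1,0,0,0,0
31,4,3,1,1,1,11,0,1,0,"living_with_partner",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,1,1,0,0
18,1,1,0,1,0,8,0,1,1,"married",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
31,3,2,0,1,1,9,0,0,1,"relationship_living_alone",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,2,2,2,2,3,3,3,3,1,1,1,1,1,1,1,1,1,0,0,0,0
25,11,0,0,0,0,9,0,1,0,"relationship_living_alone",0,70,1,1,"sometimes",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,1,1,1,0,0,0,0
26,4,3,0,1,0,8,0,1,1,"single",0,70,1,1,"seldom",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
34,5,1,1,0,1,9,0,0,0,"living_with_partner",1,48,0,1,"always",4,4,4,4,4,4,3,3,3,3,3,3,3,3,TRUE,FALSE,2,2,2,2,2,2,2,2,1,1,1,1,1,1,1,1,1,0,0,0,0
34,2,0,0,1,0,6,0,0,1,"single",1,64,1,1,"always",5,5,5,5,5,5,5,5,4,4,4,4,4,4,TRUE,FALSE,2,2,2,2,3,3,3,3,1,1,1,1,1,1,0,0,0,0,0,0,0
29,8,1,1,0,0,6,0,1,0,"relationship_living_alone",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,2,2,2,2,1,1,1,1,1,1,0,0,0,0,0,0,0
32,11,0,0,0,0,8,1,1,1,"living_with_partner",1,70,1,1,"always",5,5,5,5,5,5,5,5,5,5,5,5,5,5,TRUE,FALSE,3,3,3,3,3,3,3,3,1,1,1,1,1,1,1,1,0,0,0,0,0
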