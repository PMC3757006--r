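name,center,window,fwhm,species,unique
nu7_cytc_604,604,8,14,cyt_c_red,TRUE
cyt_750,750,8,14,cyt_c_red,FALSE
cyt_1127,1127,8,14,cyt_b_red,FALSE
cytb_1300,1300,8,14,cyt_b_red,FALSE
cytc_1310,1310,8,14,cyt_c_red,FALSE
cytb_1337,1337,8,14,cyt_b_red,TRUE
nu4_dMb_1358,1358,8,14,dMb,TRUE
nu4_oMb_1377,1377,8,14,oMb,TRUE
dMb_1556,1556,8,14,dMb,FALSE
cyt_1582,1582,8,14,cyt_c_red,FALSE
oMb_1587,1587,8,14,oMb,FALSE
dMb_1606,1606,8,14,dMb,FALSE
oMb_1640,1640,8,14,oMb,FALSE
amide_I_1658,1658,8,25,amide_I,FALSE
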