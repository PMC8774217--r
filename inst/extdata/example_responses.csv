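patient_id,device_id,item_id,level
F01,Spiromax,1,no
F01,Spiromax,2,no
F01,Spiromax,3,no
F01,Spiromax,4,no
F01,Spiromax,5,yes
F01,Spiromax,6,no
F01,Spiromax,7,no
F01,Spiromax,8,no
F01,Spiromax,9,no
F01,Spiromax,10,mild
F01,Spiromax,11,moderate
F01,Spiromax,12,yes
F01,Breezhaler,1,yes
F01,Breezhaler,2,no
F01,Breezhaler,3,no
F01,Breezhaler,4,no
F01,Breezhaler,5,yes
F01,Breezhaler,6,yes
F01,Breezhaler,7,yes
F01,Breezhaler,8,no
F01,Breezhaler,9,yes
F01,Breezhaler,10,mild
F01,Breezhaler,11,severe
F01,Breezhaler,12,no
F02,Nexthaler,1,yes
F02,Nexthaler,2,yes
F02,Nexthaler,3,no
F02,Nexthaler,4,yes
F02,Nexthaler,5,no
F02,Nexthaler,6,yes
F02,Nexthaler,7,no
F02,Nexthaler,8,yes
F02,Nexthaler,9,no
F02,Nexthaler,10,none
F02,Nexthaler,11,none
F02,Nexthaler,12,yes
F02,Breezhaler,1,yes
F02,Breezhaler,2,no
F02,Breezhaler,3,no
F02,Breezhaler,4,no
F02,Breezhaler,5,yes
F02,Breezhaler,6,yes
F02,Breezhaler,7,no
F02,Breezhaler,8,yes
F02,Breezhaler,9,no
F02,Breezhaler,10,none
F02,Breezhaler,11,severe
F02,Breezhaler,12,no
F03,Ellipta,1,yes
F03,Ellipta,2,yes
F03,Ellipta,3,no
F03,Ellipta,4,no
F03,Ellipta,5,no
F03,Ellipta,6,no
F03,Ellipta,7,no
F03,Ellipta,8,yes
F03,Ellipta,9,yes
F03,Ellipta,10,severe
F03,Ellipta,11,moderate
F03,Ellipta,12,no
F03,Spiromax,1,no
F03,Spiromax,2,no
F03,Spiromax,3,yes
F03,Spiromax,4,yes
F03,Spiromax,5,yes
F03,Spiromax,6,no
F03,Spiromax,7,no
F03,Spiromax,8,no
F03,Spiromax,9,no
F03,Spiromax,10,moderate
F03,Spiromax,11,mild
F03,Spiromax,12,yes
F04,Ellipta,1,no
F04,Ellipta,2,no
F04,Ellipta,3,no
F04,Ellipta,4,yes
F04,Ellipta,5,no
F04,Ellipta,6,yes
F04,Ellipta,7,yes
F04,Ellipta,8,yes
F04,Ellipta,9,yes
F04,Ellipta,10,moderate
F04,Ellipta,11,mild
F04,Ellipta,12,yes
F04,Breezhaler,1,no
F04,Breezhaler,2,no
F04,Breezhaler,3,yes
F04,Breezhaler,4,yes
F04,Breezhaler,5,yes
F04,Breezhaler,6,no
F04,Breezhaler,7,no
F04,Breezhaler,8,yes
F04,Breezhaler,9,no
F04,Breezhaler,10,severe
F04,Breezhaler,11,none
F04,Breezhaler,12,no
F05,Ellipta,1,no
F05,Ellipta,2,no
F05,Ellipta,3,yes
F05,Ellipta,4,no
F05,Ellipta,5,yes
F05,Ellipta,6,no
F05,Ellipta,7,yes
F05,Ellipta,8,yes
F05,Ellipta,9,yes
F05,Ellipta,10,moderate
F05,Ellipta,11,severe
F05,Ellipta,12,no
F05,Nexthaler,1,yes
F05,Nexthaler,2,yes
F05,Nexthaler,3,no
F05,Nexthaler,4,no
F05,Nexthaler,5,yes
F05,Nexthaler,6,no
F05,Nexthaler,7,yes
F05,Nexthaler,8,yes
F05,Nexthaler,9,yes
F05,Nexthaler,10,mild
F05,Nexthaler,11,severe
F05,Nexthaler,12,yes
F06,Spiromax,1,no
F06,Spiromax,2,yes
F06,Spiromax,3,no
F06,Spiromax,4,no
F06,Spiromax,5,yes
F06,Spiromax,6,yes
F06,Spiromax,7,no
F06,Spiromax,8,no
F06,Spiromax,9,no
F06,Spiromax,10,moderate
F06,Spiromax,11,moderate
F06,Spiromax,12,no
F06,Ellipta,1,no
F06,Ellipta,2,yes
F06,Ellipta,3,no
F06,Ellipta,4,yes
F06,Ellipta,5,yes
F06,Ellipta,6,yes
F06,Ellipta,7,yes
F06,Ellipta,8,no
F06,Ellipta,9,yes
F06,Ellipta,10,moderate
F06,Ellipta,11,moderate
F06,Ellipta,12,yes
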