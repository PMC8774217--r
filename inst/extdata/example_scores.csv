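patient_id,device_id,sgus_total
F01,Breezhaler,20.6
F01,Spiromax,17.1
F02,Breezhaler,21.0
F02,Nexthaler,39.0
F03,Ellipta,14.3
F03,Spiromax,23.0
F04,Breezhaler,23.8
F04,Ellipta,30.0
F05,Ellipta,17.3
F05,Nexthaler,25.8
F06,Ellipta,27.8
F06,Spiromax,15.6
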