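unit,day,true_positive,false_positive,false_negative,fp_after_triage
prototype,1,29,6,3,0
prototype,2,6,1,4,0
prototype,3,97,39,8,0
commercial,1,3,0,6,NA
commercial,2,4,1,4,NA
commercial,3,38,8,10,NA
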