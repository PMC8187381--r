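step,donor,recipient,donated,ostracised,comparison,delta_personal,delta_group,r_donor,group_rep,n_pos,n_neu,n_neg,ctr_donor,payoff_donor,payoff_recipient
1,1,2,TRUE,FALSE,similar,1,1,1,1,1,0,0,1,-0.7,1
2,1,3,FALSE,FALSE,downward,0,0,1,1,1,1,0,1,-0.7,0
3,2,1,TRUE,FALSE,upward,1,1,1,2,1,0,0,1,0.3,0.3
4,3,1,TRUE,FALSE,upward,1,0,1,2,0,0,0,NA,-0.7,1.3
5,1,2,FALSE,TRUE,downward,0,0,1,2,1,2,0,1,1.3,0.3
6,2,1,TRUE,FALSE,upward,1,1,2,3,2,0,0,1,-0.4,2.3
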