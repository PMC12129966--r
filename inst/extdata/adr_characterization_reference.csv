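dimension,category,g_icu,c19_icu,total
severity,mild,8,4,12
severity,moderate,21,27,48
severity,severe,10,15,25
mechanism,A,38,44,82
mechanism,B,1,2,3
naranjo,possible,26,29,55
naranjo,probable,12,17,29
naranjo,doubtful,1,0,1
who,unassessable_unclassifiable,0,0,0
who,conditional_unclassified,0,1,1
who,unlikely,0,1,1
who,possible,26,27,53
who,probable,13,17,30
who,certain,0,0,0
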