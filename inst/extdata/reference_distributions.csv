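system,group,category,pct
nutriscore,all,A,27
nutriscore,all,B,16
nutriscore,all,C,18
nutriscore,all,D,22
nutriscore,all,E,17
nova,all,1,19
nova,all,2,12
nova,all,3,15
nova,all,4,54
fop,all,0,57
fop,all,1,10
fop,all,2,9
fop,all,3,23
fop,all,4,1
nutriscore,cereals,A,46
nutriscore,cereals,B,7
nutriscore,cereals,C,13
nutriscore,cereals,D,15
nutriscore,cereals,E,19
nova,cereals,1,25
nova,cereals,2,0
nova,cereals,3,10
nova,cereals,4,65
fop,cereals,0,49
fop,cereals,1,13
fop,cereals,2,7
fop,cereals,3,29
fop,cereals,4,2
nutriscore,dairy,A,11
nutriscore,dairy,B,47
nutriscore,dairy,C,7
nutriscore,dairy,D,19
nutriscore,dairy,E,16
nova,dairy,1,14
nova,dairy,2,0
nova,dairy,3,31
nova,dairy,4,55
fop,dairy,0,75
fop,dairy,1,18
fop,dairy,2,6
fop,dairy,3,0
fop,dairy,4,1
nutriscore,protein_foods,A,60
nutriscore,protein_foods,B,7
nutriscore,protein_foods,C,6
nutriscore,protein_foods,D,25
nutriscore,protein_foods,E,4
nova,protein_foods,1,48
nova,protein_foods,2,2
nova,protein_foods,3,25
nova,protein_foods,4,25
fop,protein_foods,0,71
fop,protein_foods,1,14
fop,protein_foods,2,6
fop,protein_foods,3,9
fop,protein_foods,4,0
nutriscore,oils_fats,A,4
nutriscore,oils_fats,B,5
nutriscore,oils_fats,C,51
nutriscore,oils_fats,D,36
nutriscore,oils_fats,E,4
nova,oils_fats,1,0
nova,oils_fats,2,64
nova,oils_fats,3,6
nova,oils_fats,4,30
fop,oils_fats,0,50
fop,oils_fats,1,2
fop,oils_fats,2,21
fop,oils_fats,3,27
fop,oils_fats,4,0
nutriscore,sugars_others,A,4
nutriscore,sugars_others,B,20
nutriscore,sugars_others,C,18
nutriscore,sugars_others,D,25
nutriscore,sugars_others,E,33
nova,sugars_others,1,6
nova,sugars_others,2,11
nova,sugars_others,3,18
nova,sugars_others,4,75
fop,sugars_others,0,49
fop,sugars_others,1,3
fop,sugars_others,2,19
fop,sugars_others,3,38
fop,sugars_others,4,0
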