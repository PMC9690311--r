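name,group,state,energy_kcal,sugars_g,saturated_fat_g,total_fat_g,sodium_mg,fibre_g,protein_g,fvnl_pct,added_sugar,added_sat_fat,added_sodium,markers,special_category,intended_nutriscore,intended_nova,intended_fop
plain_oats,cereals,solid,375,1,1.2,7,5,10,13,0,0,0,0,,none,A,1,1
white_bread,cereals,solid,265,4,0.8,3,480,2.5,9,0,0,0,1,fermented;added_salt,none,B,3,1
sweet_breakfast_cereal,cereals,solid,400,30,2,4,350,4,7,0,1,0,1,colouring;flavouring;added_sugar,none,C,4,2
sweet_biscuits,cereals,solid,480,22,10,20,400,2,6,0,1,1,1,emulsifier;flavouring;added_sugar,none,E,4,3
salted_crackers,cereals,solid,430,2,3.5,12,700,3,10,0,0,1,1,emulsifier;added_salt,none,D,4,2
fresh_potatoes,cereals,solid,77,0.8,0,0.1,6,2.2,2,0,0,0,0,,none,A,1,0
plain_yogurt,dairy,solid,61,4.7,1.9,3.3,46,0,3.5,0,0,0,0,,none,B,1,0
whole_milk,dairy,liquid,61,4.7,2,3.3,44,0,3.2,0,0,0,0,,none,B,1,0
sweetened_dairy_drink,dairy,liquid,80,11,1.5,2,60,0,3,0,1,0,0,colouring;flavouring;added_sugar,none,B,4,2
gouda_cheese,dairy,solid,356,2,18,27,600,0,25,0,0,0,1,fermented;added_salt,cheese,D,3,3
dairy_dessert,dairy,solid,130,20,2.5,3.5,80,0,3,0,1,0,0,thickener;colouring;added_sugar,none,C,4,1
fresh_chicken,protein_foods,solid,120,0,1,3.5,70,0,22,0,0,0,0,,none,A,1,0
eggs,protein_foods,solid,143,0.4,3.1,9.5,142,0,12.6,0,0,0,0,,none,B,1,0
dried_lentils,protein_foods,solid,350,2,0.2,1.1,6,11,25,100,0,0,0,,none,A,1,1
canned_tuna,protein_foods,solid,116,0,0.9,3,320,0,26,0,0,0,1,canned;added_salt,none,A,3,0
vienna_sausage,protein_foods,solid,280,1.5,8,25,900,0,11,0,0,1,1,emulsifier;colouring;added_salt,none,E,4,3
fish_sticks,protein_foods,solid,220,1,1.5,9,450,1,13,0,0,0,1,flavouring;added_salt,none,B,4,1
sunflower_oil,oils_fats,liquid,884,0,10,100,0,0,0,0,0,0,0,vegetable_oil,added_fat,C,2,2
butter,oils_fats,solid,717,0.1,51,81,11,0,0.7,0,0,0,0,butter,added_fat,D,2,2
salted_butter,oils_fats,solid,717,0.1,51,81,600,0,0.7,0,0,0,1,butter;added_salt,added_fat,E,3,3
margarine,oils_fats,solid,717,0.5,17,80,600,0,0.2,0,0,1,1,hydrogenated_oil;emulsifier,added_fat,D,4,3
lard,oils_fats,solid,902,0,39,100,2,0,0,0,0,0,0,lard,added_fat,D,2,2
table_sugar,sugars_others,solid,387,100,0,0,1,0,0,0,0,0,0,table_sugar,none,D,2,2
cola_drink,sugars_others,liquid,42,10.6,0,0,10,0,0,0,1,0,0,colouring;flavouring;added_sugar,beverage,D,4,1
chocolate_bar,sugars_others,solid,546,52,18,31,79,3,5,0,1,1,0,emulsifier;flavouring;added_sugar,none,E,4,3
fruit_jam,sugars_others,solid,250,60,0,0.1,30,1,0.4,35,1,0,0,added_sugar,none,D,3,1
ice_cream,sugars_others,solid,207,21,7,11,80,0.7,3.5,0,1,1,0,emulsifier;flavouring;colouring;added_sugar,none,D,4,2
fruit_nectar,sugars_others,liquid,48,11,0,0.1,5,0.2,0.2,50,1,0,0,added_sugar,beverage,D,3,1
tea_leaves,sugars_others,solid,1,0.2,0,0,2,0.5,0.2,0,0,0,0,,none,B,1,0
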