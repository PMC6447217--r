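item_id,name,portion_g,energy_kcal,free_sugar_g,pufa_g,salt_g,alcohol_g,w_vegetables,w_fruits,w_whole_grains,w_dairy,w_nuts_legumes,w_oily_fish,w_red_meat
broccoli,Broccoli,80,28,0,0.1,0.05,0,1,0,0,0,0,0,0
carrots,Carrots,80,33,0,0.1,0.06,0,1,0,0,0,0,0,0
mixed_salad,Mixed salad,80,16,0,0.1,0.03,0,1,0,0,0,0,0,0
apple,Apple,100,52,0,0,0,0,0,1,0,0,0,0,0
banana,Banana,100,89,0,0.1,0,0,0,1,0,0,0,0,0
orange,Orange,130,62,0,0,0,0,0,1,0,0,0,0,0
porridge_oats,Porridge oats,40,152,0,1.1,0,0,0,0,40,0,0,0,0
wholemeal_bread,Wholemeal bread,40,87,0.6,0.6,0.4,0,0,0,34,0,0,0,0
brown_rice,Brown rice,180,200,0,0.8,0,0,0,0,60,0,0,0,0
semi_skimmed_milk,Semi-skimmed milk,200,100,0,0.1,0.25,0,0,0,0,1,0,0,0
natural_yoghurt,Natural yoghurt,125,99,0,0.1,0.2,0,0,0,0,1,0,0,0
cheddar,Cheddar cheese,30,125,0,0.2,0.5,0,0,0,0,1,0,0,0
lentils,Cooked lentils,80,93,0,0.2,0,0,0,0,0,0,1,0,0
baked_beans,Baked beans,200,162,9.8,0.6,1.2,0,0,0,0,0,1,0,0
almonds,Almonds,30,184,0,3.7,0,0,0,0,0,0,1,0,0
rapeseed_oil,Rapeseed oil,11,99,0,3.1,0,0,0,0,0,0,0,0,0
olive_oil,Olive oil,11,99,0,1.2,0,0,0,0,0,0,0,0,0
salmon,Grilled salmon,120,257,0,3.4,0.3,0,0,0,0,0,0,1,0
mackerel,Smoked mackerel,120,305,0,4.3,2.0,0,0,0,0,0,0,1,0
beef_steak,Beef steak,100,200,0,0.4,0.2,0,0,0,0,0,0,0,1
bacon,Back bacon,50,144,0,0.6,1.5,0,0,0,0,0,0,0,1
pork_sausage,Pork sausages,75,220,0.5,1.0,1.1,0,0,0,0,0,0,0,1
cola,Cola,330,139,35,0,0,0,0,0,0,0,0,0,0
milk_chocolate,Milk chocolate,50,265,25,0.5,0.1,0,0,0,0,0,0,0,0
ready_meal,Supermarket ready meal,400,450,2.0,1.5,2.5,0,0,0,0,0,0,0,0
crisps,Potato crisps,30,159,0.2,1.8,0.5,0,0,0,0,0,0,0,0
white_rice,White rice,180,234,0,0.2,0,0,0,0,0,0,0,0,0
white_pasta,White pasta,180,211,0,0.4,0,0,0,0,0,0,0,0,0
lager,Lager (pint),568,239,0,0,0,18.2,0,0,0,0,0,0,0
red_wine,Red wine (175 ml),175,119,0,0,0,16.1,0,0,0,0,0,0,0
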