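nutrient,basis,low_max,high_min
fat,food,3.0,17.5
satfat,food,1.5,5.0
sugar,food,5.0,22.5
salt,food,0.3,1.5
fat,drink,1.5,8.75
satfat,drink,0.75,2.5
sugar,drink,2.5,11.25
salt,drink,0.3,0.75
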