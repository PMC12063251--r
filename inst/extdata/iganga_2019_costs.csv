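test_id,label,category,total_cost,unit_price,quantity_per_test,useful_life_years,trips_multiplier
FPG,Personnel,recurrent,5.201,,,,
FPG,Equipment,capital,3.790,,,5,
FPG,Power,recurrent,2.508,,,,
FPG,Test kits,recurrent,972.234,,,,
FPG,Consumables,recurrent,312.622,,,,
FPG,Transport costs,patient,4422.894,,,,2
FPG,Lost productivity,patient,2573.109,,,,1.5
FPG,Meals,patient,5290.551,,,,1.5
HBA1c,Personnel,recurrent,15.332,,,,
HBA1c,Equipment,capital,184.870,,,5,
HBA1c,Power,recurrent,0.780,,,,
HBA1c,Test kits,recurrent,3516.786,,,,
HBA1c,Consumables,recurrent,312.622,,,,
HBA1c,Transport costs,patient,2211.447,,,,1
HBA1c,Lost productivity,patient,1715.406,,,,1
HBA1c,Meals,patient,3527.034,,,,1
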