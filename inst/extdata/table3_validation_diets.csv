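diet_id,ingredient_id,inclusion,energy_free
v1,corn,62.44,FALSE
v1,soybean_meal_1,26.81,FALSE
v1,wheat_bran,8.08,FALSE
v1,dicalcium_phosphate,0.97,TRUE
v1,limestone,1.10,TRUE
v1,salt,0.46,TRUE
v1,premix,0.14,TRUE
v2,corn,32.20,FALSE
v2,wheat,20.36,FALSE
v2,brown_rice,19.75,FALSE
v2,soybean_meal_1,25.05,FALSE
v2,dicalcium_phosphate,1.03,TRUE
v2,limestone,1.01,TRUE
v2,salt,0.46,TRUE
v2,premix,0.14,TRUE
v3,corn,31.13,FALSE
v3,sorghum,19.92,FALSE
v3,barley,20.24,FALSE
v3,soybean_meal_1,26.12,FALSE
v3,dicalcium_phosphate,1.01,TRUE
v3,limestone,0.98,TRUE
v3,salt,0.46,TRUE
v3,premix,0.14,TRUE
v4,corn,32.11,FALSE
v4,wheat,10.18,FALSE
v4,sorghum,9.96,FALSE
v4,brown_rice,9.87,FALSE
v4,soybean_meal_1,25.13,FALSE
v4,rice_bran,10.14,FALSE
v4,dicalcium_phosphate,0.97,TRUE
v4,limestone,1.04,TRUE
v4,salt,0.46,TRUE
v4,premix,0.14,TRUE
v5,corn,34.82,FALSE
v5,barley,10.11,FALSE
v5,wheat_flour,9.94,FALSE
v5,wheat_middling,10.01,FALSE
v5,soybean_meal_1,22.32,FALSE
v5,defatted_rice_bran,10.18,FALSE
v5,dicalcium_phosphate,0.95,TRUE
v5,limestone,1.07,TRUE
v5,salt,0.46,TRUE
v5,premix,0.14,TRUE
v6,corn,46.15,FALSE
v6,wheat,10.02,FALSE
v6,wheat_flour,9.80,FALSE
v6,fermented_soybean_meal,21.55,FALSE
v6,rice_bran,9.99,FALSE
v6,dicalcium_phosphate,0.95,TRUE
v6,limestone,0.95,TRUE
v6,salt,0.45,TRUE
v6,premix,0.14,TRUE
v7,corn,57.78,FALSE
v7,cottonseed_meal,15.13,FALSE
v7,sunflower_meal,14.42,FALSE
v7,defatted_rice_bran,10.14,FALSE
v7,dicalcium_phosphate,0.75,TRUE
v7,limestone,1.19,TRUE
v7,salt,0.45,TRUE
v7,premix,0.14,TRUE
v8,corn,61.44,FALSE
v8,soy_protein_concentrate,5.21,FALSE
v8,rapeseed_meal,19.83,FALSE
v8,rice_ddgs,11.17,FALSE
v8,dicalcium_phosphate,0.83,TRUE
v8,limestone,0.93,TRUE
v8,salt,0.45,TRUE
v8,premix,0.14,TRUE
v9,corn,61.24,FALSE
v9,soybean_meal_1,8.05,FALSE
v9,cottonseed_meal,10.18,FALSE
v9,rapeseed_meal,9.97,FALSE
v9,wheat_bran,8.06,FALSE
v9,dicalcium_phosphate,0.76,TRUE
v9,limestone,1.14,TRUE
v9,salt,0.46,TRUE
v9,premix,0.14,TRUE
v10,corn,62.85,FALSE
v10,soybean_meal_1,10.88,FALSE
v10,extruded_soybean,10.38,FALSE
v10,soy_protein_concentrate,5.21,FALSE
v10,wheat_bran,8.02,FALSE
v10,dicalcium_phosphate,0.99,TRUE
v10,limestone,1.08,TRUE
v10,salt,0.45,TRUE
v10,premix,0.14,TRUE
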