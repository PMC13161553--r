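diet_id,ingredient_id,inclusion,energy_free
d1,corn,96.96,FALSE
d1,dicalcium_phosphate,1.23,TRUE
d1,limestone,1.21,TRUE
d1,salt,0.46,TRUE
d1,premix,0.14,TRUE
d2,wheat,97.58,FALSE
d2,dicalcium_phosphate,0.88,TRUE
d2,limestone,0.95,TRUE
d2,salt,0.45,TRUE
d2,premix,0.14,TRUE
d3,sorghum,97.37,FALSE
d3,dicalcium_phosphate,1.01,TRUE
d3,limestone,1.02,TRUE
d3,salt,0.46,TRUE
d3,premix,0.14,TRUE
d4,barley,97.24,FALSE
d4,dicalcium_phosphate,1.14,TRUE
d4,limestone,1.03,TRUE
d4,salt,0.45,TRUE
d4,premix,0.14,TRUE
d5,wheat_flour,97.19,FALSE
d5,dicalcium_phosphate,1.09,TRUE
d5,limestone,1.12,TRUE
d5,salt,0.46,TRUE
d5,premix,0.14,TRUE
d6,brown_rice,96.86,FALSE
d6,dicalcium_phosphate,1.37,TRUE
d6,limestone,1.17,TRUE
d6,salt,0.46,TRUE
d6,premix,0.14,TRUE
d7,corn,37.07,FALSE
d7,wheat_middling,60.06,FALSE
d7,dicalcium_phosphate,1.07,TRUE
d7,limestone,1.20,TRUE
d7,salt,0.46,TRUE
d7,premix,0.14,TRUE
d8,corn,66.71,FALSE
d8,rice_bran,30.36,FALSE
d8,dicalcium_phosphate,1.06,TRUE
d8,limestone,1.27,TRUE
d8,salt,0.46,TRUE
d8,premix,0.14,TRUE
d9,corn,66.71,FALSE
d9,defatted_rice_bran,30.48,FALSE
d9,dicalcium_phosphate,0.96,TRUE
d9,limestone,1.25,TRUE
d9,salt,0.46,TRUE
d9,premix,0.14,TRUE
d10,corn,67.86,FALSE
d10,soybean_meal_1,29.44,FALSE
d10,dicalcium_phosphate,1.06,TRUE
d10,limestone,1.04,TRUE
d10,salt,0.46,TRUE
d10,premix,0.14,TRUE
d11,corn,68.06,FALSE
d11,soybean_meal_2,29.24,FALSE
d11,dicalcium_phosphate,1.06,TRUE
d11,limestone,1.04,TRUE
d11,salt,0.46,TRUE
d11,premix,0.14,TRUE
d12,corn,67.17,FALSE
d12,fermented_soybean_meal,30.28,FALSE
d12,dicalcium_phosphate,1.04,TRUE
d12,limestone,0.92,TRUE
d12,salt,0.45,TRUE
d12,premix,0.14,TRUE
d13,corn,70.41,FALSE
d13,enzyme_hydrolyzed_soybean_meal,26.89,FALSE
d13,dicalcium_phosphate,1.05,TRUE
d13,limestone,1.06,TRUE
d13,salt,0.45,TRUE
d13,premix,0.14,TRUE
d14,corn,71.38,FALSE
d14,extruded_soybean,25.87,FALSE
d14,dicalcium_phosphate,1.18,TRUE
d14,limestone,0.98,TRUE
d14,salt,0.45,TRUE
d14,premix,0.14,TRUE
d15,corn,76.45,FALSE
d15,soy_protein_concentrate,20.80,FALSE
d15,dicalcium_phosphate,1.05,TRUE
d15,limestone,1.11,TRUE
d15,salt,0.45,TRUE
d15,premix,0.14,TRUE
d16,corn,76.88,FALSE
d16,cottonseed_meal,20.33,FALSE
d16,dicalcium_phosphate,0.90,TRUE
d16,limestone,1.29,TRUE
d16,salt,0.46,TRUE
d16,premix,0.14,TRUE
d17,corn,72.60,FALSE
d17,rapeseed_meal,25.00,FALSE
d17,dicalcium_phosphate,0.85,TRUE
d17,limestone,0.95,TRUE
d17,salt,0.46,TRUE
d17,premix,0.14,TRUE
d18,corn,71.90,FALSE
d18,sunflower_meal,25.46,FALSE
d18,dicalcium_phosphate,0.98,TRUE
d18,limestone,1.06,TRUE
d18,salt,0.46,TRUE
d18,premix,0.15,TRUE
d19,corn,71.22,FALSE
d19,rice_ddgs,25.97,FALSE
d19,dicalcium_phosphate,1.12,TRUE
d19,limestone,1.10,TRUE
d19,salt,0.45,TRUE
d19,premix,0.14,TRUE
d20,corn,71.94,FALSE
d20,wheat_bran,25.19,FALSE
d20,dicalcium_phosphate,0.91,TRUE
d20,limestone,1.36,TRUE
d20,salt,0.46,TRUE
d20,premix,0.14,TRUE
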