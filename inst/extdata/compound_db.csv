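name,formula,food_sources,food_group,ionization_products,standard_mass_match,standard_rt_match,msn_match,literature_spectral_match,class_only
Pyrogallol glucuronide,C12H14O9,garden peas;baked beans;peanuts;tofu,legumes,[M-H]1-,TRUE,TRUE,TRUE,FALSE,FALSE
Pyrogallol sulfate,C6H6O6S,garden peas;baked beans;peanuts;tofu,legumes,[M-H]1-;[M-H]1-13C;[M-H]1-34S,TRUE,TRUE,TRUE,FALSE,FALSE
Trigonelline,C7H7NO2,garden peas;baked beans;peanuts;tofu,legumes,[M+H]1+13C;[M+Na]1+;[M+Na]1+13C;[M+K]1+;[M+K]1+13C;[M+K]1+41K,TRUE,TRUE,TRUE,FALSE,FALSE
Eugenol glucuronide,C16H20O8,chicken curry,curry,[M-H]1-;[M-H-gluc]1-;[M-H-gluc]1-13C,TRUE,TRUE,TRUE,FALSE,FALSE
Eugenol sulfate,C10H12O5S,chicken curry,curry,[M-H]1-;[M-H]1-34S,TRUE,TRUE,TRUE,FALSE,FALSE
2-Furoylglycine,C7H7NO4,toasted wholemeal bread;meat pie,heated,[M+Na]1+;[M+K]1+;[M+2Na-H]1+;[M+KNa-H]1+;[M-H]1-,TRUE,TRUE,TRUE,FALSE,FALSE
Furaneol sulfate,C6H8O6S,strawberries;tomato soup;tomato pasta,berries_tomato,[M-H]1-;[M-H]1-13C;[M-H]1-34S,TRUE,TRUE,TRUE,FALSE,FALSE
Furaneol glucuronide,C12H16O9,strawberries;tomato soup;tomato pasta,berries_tomato,[M-H]1-,TRUE,TRUE,TRUE,FALSE,FALSE
Mesifurane sulfate,C7H10O6S,strawberries;tomato soup;tomato pasta,berries_tomato,[M-H]1-,FALSE,FALSE,FALSE,TRUE,FALSE
Norfuraneol sulfate,C5H6O6S,toasted wholemeal bread;meat pie;strawberries;tomato soup,heated,[M-H]1-;[M-H]1-34S,TRUE,TRUE,TRUE,FALSE,FALSE
Acetylformoine sulfate,C6H8O7S,toasted wholemeal bread;meat pie;strawberries;tomato soup,heated,[M-H]1-,FALSE,FALSE,FALSE,FALSE,TRUE
Acetylformoine glucuronide,C12H16O10,toasted wholemeal bread;meat pie;strawberries;tomato soup,heated,[M-H]1-;[M-H]1-13C,FALSE,FALSE,FALSE,FALSE,TRUE
Acesulfame potassium,C4H4KNO4S,low-calorie beverage,low_cal_beverage,[M-K]1-;[M-K]1-13C;[M-K]1-34S,TRUE,TRUE,TRUE,FALSE,FALSE
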