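name,formula,ionization_products,source_foods,food_group,lag_h,halflife_h,spike_magnitude
Pyrogallol sulfate,C6H6O6S,[M-H]1-;[M-H]1-13C;[M-H]1-34S,garden peas;baked beans;peanuts;tofu,legumes,0.5,6,5
Trigonelline,C7H7NO2,[M+Na]1+;[M+K]1+,garden peas;baked beans;peanuts;tofu,legumes,0.5,8,4
Eugenol sulfate,C10H12O5S,[M-H]1-;[M-H]1-34S,chicken curry,curry,0.5,5,4
2-Furoylglycine,C7H7NO4,[M-H]1-;[M+Na]1+,toasted wholemeal bread;meat pie,heated,0.5,5,3
Acesulfame potassium,C4H4KNO4S,[M-K]1-,low-calorie beverage,low_cal_beverage,0.5,6,5
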