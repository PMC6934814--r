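period,diet,nutrient,percent,grams
youth,predicted,carbohydrates,54,269
youth,predicted,protein,11,57
youth,predicted,sat_fat,14,33
youth,predicted,mono_fat,14,30
youth,predicted,poly_fat,7,14
early_middle_age,predicted,carbohydrates,54,269
early_middle_age,predicted,protein,7,34
early_middle_age,predicted,sat_fat,17,37
early_middle_age,predicted,mono_fat,16,37
early_middle_age,predicted,poly_fat,6,14
late_middle_age,predicted,carbohydrates,50,251
late_middle_age,predicted,protein,6,31
late_middle_age,predicted,sat_fat,17,38
late_middle_age,predicted,mono_fat,18,40
late_middle_age,predicted,poly_fat,9,19
late_age,predicted,carbohydrates,43,218
late_age,predicted,protein,17,84
late_age,predicted,sat_fat,16,35
late_age,predicted,mono_fat,15,33
late_age,predicted,poly_fat,9,19
youth,mean,carbohydrates,55,275
youth,mean,protein,12,58
youth,mean,sat_fat,15,34
youth,mean,mono_fat,14,31
youth,mean,poly_fat,4,10
early_middle_age,mean,carbohydrates,51,254
early_middle_age,mean,protein,12,60
early_middle_age,mean,sat_fat,15,35
early_middle_age,mean,mono_fat,16,35
early_middle_age,mean,poly_fat,6,13
late_middle_age,mean,carbohydrates,48,241
late_middle_age,mean,protein,13,64
late_middle_age,mean,sat_fat,14,32
late_middle_age,mean,mono_fat,17,37
late_middle_age,mean,poly_fat,8,17
late_age,mean,carbohydrates,50,247
late_age,mean,protein,12,61
late_age,mean,sat_fat,13,29
late_age,mean,mono_fat,17,38
late_age,mean,poly_fat,8,17
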