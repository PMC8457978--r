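component	weight	units
energy	0.180	kcal/d
carbohydrate	0.097	g/d
protein	0.021	g/d
total_fat	0.298	g/d
saturated_fat	0.429	g/d
mufa	-0.009	g/d
pufa	-0.337	g/d
omega3	-0.436	g/d
omega6	-0.159	g/d
trans_fat	0.229	g/d
cholesterol	0.110	mg/d
fiber	-0.663	g/d
vitamin_a	-0.401	RE/d
beta_carotene	-0.584	ug/d
vitamin_c	-0.424	mg/d
vitamin_d	-0.446	ug/d
vitamin_e	-0.419	mg/d
thiamin	-0.098	mg/d
riboflavin	-0.068	mg/d
niacin	-0.246	mg/d
vitamin_b6	-0.365	mg/d
folate	-0.190	ug/d
vitamin_b12	0.106	ug/d
iron	0.032	mg/d
magnesium	-0.484	mg/d
zinc	-0.313	mg/d
selenium	-0.191	ug/d
flavonoids	-0.616	mg/d
isoflavones	-0.593	mg/d
anthocyanidins	-0.131	mg/d
green_black_tea	-0.536	g/d
onion	-0.301	g/d
pepper	-0.131	g/d
thyme_oregano	-0.102	g/d
rosemary	-0.013	g/d
eugenol	-0.140	g/d
alcohol	-0.278	g/d
caffeine	-0.110	mg/d
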