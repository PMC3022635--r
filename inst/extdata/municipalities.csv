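id,x,y,population,urbanisation_class
ville,10000,10000,25000,major_pole
bourg,4000,14000,3200,suburban
colline,16500,13500,900,rural_under_influence
riviere,3500,4500,650,rural_under_influence
foret,17000,3000,420,rural_outside_influence
plaine,11500,2500,1100,rural_under_influence
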