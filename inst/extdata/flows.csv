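origin_id,destination_id,commuters
ville,ville,8200
bourg,ville,820
bourg,bourg,310
colline,ville,190
colline,bourg,25
colline,colline,85
riviere,ville,150
riviere,riviere,60
foret,ville,70
foret,plaine,30
foret,foret,45
plaine,ville,260
plaine,plaine,120
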