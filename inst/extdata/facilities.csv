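municipality_id,facility_type,count
ville,bakeries,12
bourg,bakeries,3
colline,bakeries,1
riviere,bakeries,0
foret,bakeries,0
plaine,bakeries,1
ville,hyper_supermarkets,3
bourg,hyper_supermarkets,1
colline,hyper_supermarkets,0
riviere,hyper_supermarkets,0
foret,hyper_supermarkets,0
plaine,hyper_supermarkets,0
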