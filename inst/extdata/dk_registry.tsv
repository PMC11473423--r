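region	tissue_class	frontolimbic	area_weight
bankssts	cortical	FALSE	1000
caudalanteriorcingulate	cortical	TRUE	700
caudalmiddlefrontal	cortical	FALSE	2300
cuneus	cortical	FALSE	1500
entorhinal	cortical	FALSE	400
frontalpole	cortical	FALSE	300
fusiform	cortical	TRUE	3400
inferiorparietal	cortical	TRUE	5200
inferiortemporal	cortical	FALSE	3400
insula	cortical	FALSE	2300
isthmuscingulate	cortical	FALSE	1000
lateraloccipital	cortical	FALSE	4400
lateralorbitofrontal	cortical	TRUE	2700
lingual	cortical	FALSE	3100
medialorbitofrontal	cortical	TRUE	1900
middletemporal	cortical	FALSE	3500
paracentral	cortical	FALSE	1600
parahippocampal	cortical	FALSE	800
parsopercularis	cortical	FALSE	1700
parsorbitalis	cortical	FALSE	700
parstriangularis	cortical	FALSE	1600
pericalcarine	cortical	FALSE	1400
postcentral	cortical	FALSE	4400
posteriorcingulate	cortical	TRUE	1300
precentral	cortical	FALSE	5300
precuneus	cortical	FALSE	3900
rostralanteriorcingulate	cortical	TRUE	800
rostralmiddlefrontal	cortical	FALSE	6300
superiorfrontal	cortical	FALSE	7400
superiorparietal	cortical	FALSE	5500
superiortemporal	cortical	TRUE	3800
supramarginal	cortical	FALSE	3800
temporalpole	cortical	FALSE	500
transversetemporal	cortical	FALSE	400
thalamus	subcortical	TRUE	NA
amygdala	subcortical	TRUE	NA
hippocampus	subcortical	TRUE	NA
caudate	subcortical	FALSE	NA
putamen	subcortical	FALSE	NA
pallidum	subcortical	FALSE	NA
accumbens	subcortical	FALSE	NA
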