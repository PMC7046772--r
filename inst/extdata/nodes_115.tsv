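region_label	hemisphere	lobe	node_class
Left precentral gyrus	left	frontal	cortical
Right precentral gyrus	right	frontal	cortical
Left superior frontal gyrus	left	frontal	cortical
Right superior frontal gyrus	right	frontal	cortical
Left middle frontal gyrus	left	frontal	cortical
Right middle frontal gyrus	right	frontal	cortical
Left postcentral gyrus	left	parietal	cortical
Right postcentral gyrus	right	parietal	cortical
Left superior parietal lobule	left	parietal	cortical
Right superior parietal lobule	right	parietal	cortical
Left precuneus	left	parietal	cortical
Right precuneus	right	parietal	cortical
Left middle temporal gyrus	left	temporal	cortical
Right middle temporal gyrus	right	temporal	cortical
Left thalamus	left	subcortical	subcortical
Right thalamus	right	subcortical	subcortical
Left putamen	left	subcortical	subcortical
Right putamen	right	subcortical	subcortical
Left caudal anterior cingulate gyrus	left	frontal	cortical
Right caudal anterior cingulate gyrus	right	frontal	cortical
Left rostral anterior cingulate gyrus	left	frontal	cortical
Right rostral anterior cingulate gyrus	right	frontal	cortical
Left middle cingulate gyrus	left	frontal	cortical
Right middle cingulate gyrus	right	frontal	cortical
Left lateral orbitofrontal cortex	left	frontal	cortical
Right lateral orbitofrontal cortex	right	frontal	cortical
Left medial orbitofrontal cortex	left	frontal	cortical
Right medial orbitofrontal cortex	right	frontal	cortical
Left pars opercularis	left	frontal	cortical
Right pars opercularis	right	frontal	cortical
Left pars orbitalis	left	frontal	cortical
Right pars orbitalis	right	frontal	cortical
Left pars triangularis	left	frontal	cortical
Right pars triangularis	right	frontal	cortical
Left paracentral lobule	left	frontal	cortical
Right paracentral lobule	right	frontal	cortical
Left frontal operculum	left	frontal	cortical
Right frontal operculum	right	frontal	cortical
Left frontal pole	left	frontal	cortical
Right frontal pole	right	frontal	cortical
Left gyrus rectus	left	frontal	cortical
Right gyrus rectus	right	frontal	cortical
Left subcallosal area	left	frontal	cortical
Right subcallosal area	right	frontal	cortical
Left superior frontal gyrus medial segment	left	frontal	cortical
Right superior frontal gyrus medial segment	right	frontal	cortical
Left supplementary motor cortex	left	frontal	cortical
Right supplementary motor cortex	right	frontal	cortical
Left central operculum	left	frontal	cortical
Right central operculum	right	frontal	cortical
Left inferior parietal lobule	left	parietal	cortical
Right inferior parietal lobule	right	parietal	cortical
Left supramarginal gyrus	left	parietal	cortical
Right supramarginal gyrus	right	parietal	cortical
Left angular gyrus	left	parietal	cortical
Right angular gyrus	right	parietal	cortical
Left parietal operculum	left	parietal	cortical
Right parietal operculum	right	parietal	cortical
Left posterior cingulate gyrus	left	parietal	cortical
Right posterior cingulate gyrus	right	parietal	cortical
Left isthmus cingulate gyrus	left	parietal	cortical
Right isthmus cingulate gyrus	right	parietal	cortical
Left cuneus	left	occipital	cortical
Right cuneus	right	occipital	cortical
Left lateral occipital cortex	left	occipital	cortical
Right lateral occipital cortex	right	occipital	cortical
Left lingual gyrus	left	occipital	cortical
Right lingual gyrus	right	occipital	cortical
Left pericalcarine cortex	left	occipital	cortical
Right pericalcarine cortex	right	occipital	cortical
Left calcarine cortex	left	occipital	cortical
Right calcarine cortex	right	occipital	cortical
Left occipital pole	left	occipital	cortical
Right occipital pole	right	occipital	cortical
Left occipital fusiform gyrus	left	occipital	cortical
Right occipital fusiform gyrus	right	occipital	cortical
Left superior temporal gyrus	left	temporal	cortical
Right superior temporal gyrus	right	temporal	cortical
Left inferior temporal gyrus	left	temporal	cortical
Right inferior temporal gyrus	right	temporal	cortical
Left transverse temporal gyrus	left	temporal	cortical
Right transverse temporal gyrus	right	temporal	cortical
Left entorhinal cortex	left	temporal	cortical
Right entorhinal cortex	right	temporal	cortical
Left parahippocampal gyrus	left	temporal	cortical
Right parahippocampal gyrus	right	temporal	cortical
Left fusiform gyrus	left	temporal	cortical
Right fusiform gyrus	right	temporal	cortical
Left temporal pole	left	temporal	cortical
Right temporal pole	right	temporal	cortical
Left planum polare	left	temporal	cortical
Right planum polare	right	temporal	cortical
Left planum temporale	left	temporal	cortical
Right planum temporale	right	temporal	cortical
Left anterior insula	left	insula	cortical
Right anterior insula	right	insula	cortical
Left posterior insula	left	insula	cortical
Right posterior insula	right	insula	cortical
Left caudate nucleus	left	subcortical	subcortical
Right caudate nucleus	right	subcortical	subcortical
Left globus pallidus	left	subcortical	subcortical
Right globus pallidus	right	subcortical	subcortical
Left nucleus accumbens	left	subcortical	subcortical
Right nucleus accumbens	right	subcortical	subcortical
Left hippocampus	left	subcortical	subcortical
Right hippocampus	right	subcortical	subcortical
Left amygdala	left	subcortical	subcortical
Right amygdala	right	subcortical	subcortical
Left ventral diencephalon	left	subcortical	subcortical
Right ventral diencephalon	right	subcortical	subcortical
Left basal forebrain	left	subcortical	subcortical
Right basal forebrain	right	subcortical	subcortical
Left cerebellum	left	other	subcortical
Right cerebellum	right	other	subcortical
Brainstem	midline	other	subcortical
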