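hook_id	source_locus	category	annotation
ALS1	Afu2g12630	housekeeping	acetolactate synthase
HMGR1	Afu1g11230	housekeeping	3-hydroxy-3-methylglutaryl-CoA reductase
IMPDH1	Afu4g10110	housekeeping	inosine-5'-monophosphate dehydrogenase
ADSS1	Afu3g06480	housekeeping	adenylosuccinate synthetase
PSMB1	Afu5g09530	housekeeping	proteasome subunit beta
DAHP1	Afu1g05910	housekeeping	phospho-2-dehydro-3-deoxyheptonate aldolase
SUR2	Afu6g07240	housekeeping	sphingolipid C4-hydroxylase
TUBB1	Afu1g10910	housekeeping	beta-tubulin
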