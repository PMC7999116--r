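roc_threshold_reference.csv

Published reference table of antero-posterior displacement threshold points
(mm) identified by ROC curves, per bone segment, delta-area cutoff (percent)
and pharyngeal subregion, with the corresponding Youden indices and AUCs.
Secondary columns carry the lower of the two peaks where the Youden index
was bimodal. Note: the running text accompanying the original table quotes
the mandibular 100% cut-offs as +5.3 and +6.3 mm, which disagrees with the
tabulated row (5.2 / 5.2 / 6.2); this file stores the tabulated values.
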