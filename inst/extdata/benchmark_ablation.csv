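model,precision,recall,specificity,accuracy,f1,auc
title_only,69.19,72.64,86.14,82.09,70.87,86.71
abstract_only,72.22,71.14,88.27,83.13,71.68,89.72
title_journal,58.87,77.61,76.76,77.01,66.95,86.98
title_abstract,70.40,78.11,85.93,83.58,74.06,89.15
abstract_journal,71.95,79.10,86.78,84.48,75.36,89.98
full,71.55,82.59,85.92,84.93,76.67,91.84
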