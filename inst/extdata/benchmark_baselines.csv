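model,precision,recall,specificity,accuracy,f1,auc
random_forest,59.11,79.10,76.54,77.31,67.66,85.28
l1_logistic,75.00,52.24,92.54,80.45,61.58,85.64
bilstm,64.86,59.70,86.14,78.21,62.18,82.21
bilstm_attention,66.67,68.66,85.29,80.30,67.65,83.63
textcnn,66.67,61.69,86.78,79.25,64.08,85.22
textrcnn,61.54,79.60,78.68,78.96,69.41,86.15
finetuned_transformer,71.69,78.11,86.78,84.18,74.76,89.59
attention_screener,71.55,82.59,85.92,84.93,76.67,91.84
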