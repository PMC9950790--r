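model	accuracy	accuracy_sd	precision	precision_sd	recall	recall_sd	f1	f1_sd	auroc	auroc_sd	auprc	auprc_sd
knn	0.827	0.012	0.848	0.012	0.965	0.013	0.903	0.008	0.651	0.024	0.309	0.033
nb	0.813	0.014	0.845	0.012	0.949	0.013	0.894	0.009	0.617	0.026	0.269	0.031
svm_rbf	0.834	0.011	0.838	0.012	0.992	0.006	0.909	0.007	0.657	0.027	0.330	0.038
rf	0.849	0.012	0.861	0.012	0.977	0.008	0.915	0.007	0.739	0.024	0.460	0.039
adaboost	0.833	0.011	0.834	0.012	0.998	0.004	0.909	0.007	0.667	0.027	0.317	0.038
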