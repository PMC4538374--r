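method,kind,auc_median,auc_sd,rsd,stability,stability_sd
Nnet,classifier,0.57,0.04,6.41,NA,NA
DT,classifier,0.54,0.04,7.89,NA,NA
BST,classifier,0.58,0.04,8.23,NA,NA
BY,classifier,0.64,0.05,0.86,NA,NA
BAG,classifier,0.64,0.03,5.56,NA,NA
RF,classifier,0.66,0.03,3.52,NA,NA
MARS,classifier,0.61,0.03,6.98,NA,NA
SVM,classifier,0.61,0.03,6.39,NA,NA
DA,classifier,0.61,0.02,6.37,NA,NA
NN,classifier,0.61,0.02,4.08,NA,NA
GLM,classifier,0.63,0.02,2.19,NA,NA
PLSR,classifier,0.63,0.02,2.24,NA,NA
RELF,feature_selection,0.61,0.04,NA,0.91,0.05
FSCR,feature_selection,0.62,0.04,NA,0.78,0.08
GINI,feature_selection,0.62,0.04,NA,0.68,0.10
CHSQ,feature_selection,0.60,0.04,NA,0.69,0.09
JMI,feature_selection,0.61,0.04,NA,0.68,0.05
CIFE,feature_selection,0.60,0.03,NA,0.69,0.05
DISR,feature_selection,0.62,0.05,NA,0.69,0.05
MIM,feature_selection,0.61,0.04,NA,0.94,0.02
CMIM,feature_selection,0.62,0.04,NA,0.73,0.04
ICAP,feature_selection,0.61,0.03,NA,0.72,0.04
TSCR,feature_selection,0.61,0.02,NA,0.78,0.12
MRMR,feature_selection,0.63,0.06,NA,0.74,0.03
MIFS,feature_selection,0.63,0.06,NA,0.80,0.03
WLCX,feature_selection,0.65,0.02,NA,0.84,0.05
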