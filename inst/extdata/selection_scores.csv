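model,count_error,accuracy,f1,fnr,fpr,tnr,tpr
mIoU,0.669,98.42,96.09,4.66,0.79,99.21,95.34
mRecall,1.686,97.22,93.39,3.42,2.62,97.38,96.58
mPrecision,1.561,94.94,85.82,24.84,0,100,75.16
m(0.3P+0.7R),1.263,97.22,93.39,3.42,2.62,97.38,96.58
m(0.4P+0.6R),0.651,98.23,95.72,2.80,1.51,98.49,97.20
m(0.5P+0.5R),0.611,98.48,96.30,3.11,1.11,98.89,96.89
m(0.6P+0.4R),0.907,98.42,96.04,5.90,0.48,99.52,94.10
m(0.7P+0.3R),1.561,96.33,90.10,18.01,0,100,81.99
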