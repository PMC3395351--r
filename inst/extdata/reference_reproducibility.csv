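quantity,mean,mean_abs_diff,cv_printed
early_liver_density,28.0,4.14,10.4
early_lung_density,12.8,0.94,5.2
early_mediastinum_density,4.8,1.25,18.4
early_heart_density,9.3,0.20,1.5
early_lumen_density,5.0,0.33,4.7
delayed_liver_density,26.6,3.03,8.1
delayed_lung_density,10.5,0.69,4.6
delayed_mediastinum_density,4.1,0.50,8.7
delayed_heart_density,8.2,0.23,1.9
delayed_lumen_density,4.4,0.34,5.4
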