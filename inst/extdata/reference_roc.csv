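variable,auc,se,p_ref,ci_lower,ci_upper,significant
Gait Speed (m/s),0.200,0.035,NA,0.130,0.269,TRUE
Time Up and Go (s),0.801,0.036,NA,0.730,0.872,TRUE
SD left SWING,0.682,0.044,NA,0.595,0.768,TRUE
SD right SWING,0.703,0.043,NA,0.620,0.787,TRUE
SD left SWING %,0.674,0.045,NA,0.585,0.763,TRUE
SD right SWING %,0.740,0.041,NA,0.660,0.819,TRUE
SD left STANCE %,0.674,0.045,NA,0.585,0.763,TRUE
SD right STANCE %,0.740,0.041,NA,0.660,0.819,TRUE
SD DOUBLE SUPPORT %,0.643,0.039,NA,0.566,0.720,TRUE
IQR left SWING,0.778,0.037,NA,0.704,0.851,TRUE
IQR right SWING,0.733,0.041,NA,0.654,0.813,TRUE
IQR left SWING %,0.776,0.037,NA,0.703,0.848,TRUE
IQR right SWING %,0.820,0.034,NA,0.754,0.886,TRUE
IQR left STANCE,0.639,0.045,0.0036,0.551,0.727,FALSE
IQR right STANCE,0.667,0.044,NA,0.580,0.754,TRUE
IQR left STANCE %,0.776,0.037,NA,0.703,0.848,TRUE
IQR right STANCE %,0.820,0.034,NA,0.754,0.886,TRUE
IQR DOUBLE SUPPORT %,0.634,0.040,0.0012,0.556,0.712,FALSE
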