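endpoint,phase,group,mean,sd,n,unit,source
HAMD,before,control,38.67,3.05,59,points,trial psychological-state summary
HAMD,before,experiment,38.55,2.97,59,points,trial psychological-state summary
HAMD,after,control,23.52,2.04,59,points,trial psychological-state summary
HAMD,after,experiment,16.49,1.2,59,points,trial psychological-state summary
HAMA,before,control,45.32,2.45,59,points,trial psychological-state summary
HAMA,before,experiment,44.78,2.33,59,points,trial psychological-state summary
HAMA,after,control,25.98,1.89,59,points,trial psychological-state summary
HAMA,after,experiment,17.48,1.37,59,points,trial psychological-state summary
physical_function,after,control,57.22,4.75,59,points,trial quality-of-life summary
physical_function,after,experiment,89.43,5.42,59,points,trial quality-of-life summary
social_function,after,control,56.85,4.25,59,points,trial quality-of-life summary
social_function,after,experiment,83.44,4.87,59,points,trial quality-of-life summary
pain,after,control,42.43,3.74,59,points,trial quality-of-life summary
pain,after,experiment,23.71,3.83,59,points,trial quality-of-life summary
cognitive_function,after,control,61.2,4.11,59,points,trial quality-of-life summary
cognitive_function,after,experiment,79.86,2.44,59,points,trial quality-of-life summary
NSE,after,control,23.52,1.87,59,ng/mL,trial tumour-marker summary
NSE,after,experiment,18.43,1.05,59,ng/mL,trial tumour-marker summary
CEA,after,control,20.15,1.23,59,ng/mL,trial tumour-marker summary
CEA,after,experiment,14.03,1.12,59,ng/mL,trial tumour-marker summary
SCC,after,control,1.36,0.15,59,ng/mL,trial tumour-marker summary
SCC,after,experiment,0.95,0.33,59,ng/mL,trial tumour-marker summary
CA19_9,after,control,96.83,11.33,59,U/mL,trial tumour-marker summary
CA19_9,after,experiment,64.72,8.45,59,U/mL,trial tumour-marker summary
age,baseline,control,54.32,13.45,59,years,trial baseline table
age,baseline,experiment,56.71,11.05,59,years,trial baseline table
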