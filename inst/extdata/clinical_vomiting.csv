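group,degree,count,printed_percent,source
experiment,0,27,45.76,trial vomiting-grade table
experiment,I,24,40.68,trial vomiting-grade table
experiment,II,7,11.86,trial vomiting-grade table
experiment,III,1,1.69,trial vomiting-grade table
experiment,IV,0,0.00,trial vomiting-grade table
control,0,7,11.86,trial vomiting-grade table
control,I,12,20.34,trial vomiting-grade table
control,II,20,33.90,trial vomiting-grade table
control,III,11,18.64,trial vomiting-grade table
control,IV,9,15.69,trial vomiting-grade table (printed percent differs from 9/59 = 15.25)
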