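item,category,control,experiment,source
gender,male,37,34,trial baseline table
gender,female,22,25,trial baseline table
education,junior_high_or_below,28,24,trial baseline table
education,high_school_or_junior_college,17,21,trial baseline table
education,bachelor_or_above,14,14,trial baseline table
smoking,smoker,47,44,trial baseline table
smoking,nonsmoker,12,15,trial baseline table
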