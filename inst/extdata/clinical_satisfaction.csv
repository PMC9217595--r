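group,category,count,printed_percent,source
experiment,very_satisfied,47,,trial satisfaction summary
experiment,basically_satisfied,10,,trial satisfaction summary
experiment,dissatisfied,2,,trial satisfaction summary
control,overall_satisfied,,81.36,trial satisfaction summary (no count split published)
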