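"sample","ct_target","ct_reference","ct_target_cal","ct_ref_cal"
"del_het",26,25,25,25
"diploid",25,25,25,25
"dup_het",24.4150374992788,25,25,25
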