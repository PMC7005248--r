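.datatable.aware <- TRUE

utils::globalVariables(c("pos_o", "pos_r", "contig_o", "contig_r", "diag",
                         "o_start", "o_end", "r_start", "r_end", "g", "."))
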