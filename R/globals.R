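# data.table non-standard evaluation symbols
utils::globalVariables(c(
  ".", ".N", "a1", "a2", "allele1", "allele2", "contig", "correct",
  "coverage", "dosage", "dosage_accuracy", "emitted", "fnr", "fpr", "frag",
  "g", "gg", "is_error", "isize", "M", "n", "n_p", "nqs", "nqsb", "nt",
  "o_rd", "pos", "q2", "qs", "ref_dosage", "score", "t_rd", "true_nt",
  "weight", "alt_nt", "ref_nt", "post", "ploidy"))
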