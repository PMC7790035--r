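# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "N", "snp_id", "chrom", "pos", "a1", "a2", "z", "n", "p",
  "b_a1", "b_a2", "z_a", "z_b", "n_a", "n_b", "p_a", "p_b",
  "block", "slot", "ld_score", "conjfdr", "condfdr_a_given_b",
  "condfdr_b_given_a", "conjfdr_ab", "conjfdr_ac", "conjfdr_bc",
  "trio_conjfdr", "lead_conjfdr", "lead_snp", "n_ind_sig", "n_cand",
  "is_lead", "locus", "i", "cum_pos", "sig", "start", "end",
  "expected", "observed", "stratum"))
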