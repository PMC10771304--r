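# Hand-built Ct table with flat replicate values:
# dCt(treated) and dCt(control) are set exactly, so every ddCt quantity
# has a closed-form expected value.
flat_qpcr <- function(dct_treated = 5, dct_control = 4) {
  samples <- c("T1", "T2", "C1", "C2")
  groups <- c("treated", "treated", "control", "control")
  dct <- c(dct_treated, dct_treated, dct_control, dct_control)
  do.call(rbind, lapply(seq_along(samples), function(i) {
    rbind(
      data.frame(sample_id = samples[i], group = groups[i],
                 gene_id = "TARGET1", role = "target", replicate = 1:2,
                 ct = 20 + dct[i], stringsAsFactors = FALSE),
      data.frame(sample_id = samples[i], group = groups[i],
                 gene_id = "GAPDH", role = "housekeeping", replicate = 1:2,
                 ct = 20, stringsAsFactors = FALSE))
  }))
}
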