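#!/usr/bin/env Rscript
# Photobleaching-step analysis: simulate traces of monomeric, dimeric and
# dodecameric complexes at step SNR 5 and classify each as single-, two- or
# multi-step. Monomer controls bleach in one step; intact holoenzymes give
# unresolvable multi-step decays, as in real recordings.

suppressMessages(library(oligostate))
dir.create("results", showWarnings = FALSE)

n_traces <- 300
rows <- list()
for (n_sub in c(1L, 2L, 12L)) {
  cls <- vapply(seq_len(n_traces), function(i) {
    tr <- simulate_bleach_trace(n_sub, nu = 0, unit_intensity = 100,
                                noise_sd = 20, seed = 5000 * n_sub + i)
    as.character(classify_steps(tr))
  }, character(1))
  tab <- table(factor(cls, levels = c("single", "double", "multi")))
  rows[[as.character(n_sub)]] <- data.frame(
    n_fluorophores = n_sub, t(as.matrix(tab)))
  message(sprintf("n = %2d fluorophores: single %3d, double %3d, multi %3d",
                  n_sub, tab["single"], tab["double"], tab["multi"]))
}
write.csv(do.call(rbind, rows), "results/bleach_step_classes.csv",
          row.names = FALSE)
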