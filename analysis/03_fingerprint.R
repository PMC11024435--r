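#!/usr/bin/env Rscript
# MEMO spectral fingerprints: binned MS2 fragment peaks and neutral losses
# per extract, assembled into the extract-by-token count matrix used by
# the Similarity Component.

suppressMessages(library(extractprio))

scenario <- read_scenario("results/scenario")
memo <- build_memo_matrix(scenario$spectra, bin_width = 0.01,
                          loss_range = c(10, 200))
write_memo_tsv(memo, "results/memo_matrix.tsv")

cat("MEMO matrix:", nrow(memo), "extracts x", ncol(memo), "tokens\n")
cat("token types:",
    sum(startsWith(colnames(memo), "peak@")), "peaks,",
    sum(startsWith(colnames(memo), "loss@")), "losses\n")
cat("written to results/memo_matrix.tsv\n")
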