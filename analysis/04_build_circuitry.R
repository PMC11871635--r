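#!/usr/bin/env Rscript

# Stage 4: regulatory-graph construction, the strict "more than two
# self-motifs" autoregulation rule, exhaustive circuitry enumeration and
# occurrence-frequency scoring.

suppressMessages(library(crcscan))

params <- crc_params()
counts <- read.delim("results/counts.tsv", stringsAsFactors = FALSE)
truth <- read_truth("results/synthetic/truth.json")

graph <- build_graph(counts, tfs = unique(counts$target_tf),
                     edge_min = params$edge_min)
auto <- autoregulated_tfs(graph, params$self_threshold)
circ <- enumerate_circuitries(graph, min_size = params$min_size,
                              self_threshold = params$self_threshold)
scored <- score_circuitries(circ)
report_crc(graph, scored, "results", plot_top = TRUE)

cat(sprintf("Autoregulated TFs (self > %g): %s\n", params$self_threshold,
            paste(auto, collapse = ", ")))
cat(sprintf("Circuitries enumerated: %d\n", nrow(scored)))
cat("Top circuitries:\n")
print(head(data.frame(rank = scored$rank, members = scored$key,
                      size = scored$size,
                      score = round(scored$score, 3),
                      maximal = scored$is_maximal), 5))
top <- top_circuitry(scored)
cat(sprintf("\nTop circuitry %s planted core (%s)\n",
            if (setequal(top, truth$core_tfs)) "MATCHES" else "differs from",
            paste(truth$core_tfs, collapse = ",")))
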