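#!/usr/bin/env Rscript

# Stage 3: FIMO-style motif scanning. Super-enhancer regions assigned to a
# TF are extended 500 bp on both sides and every TF motif is scanned over
# both strands with exact DP p-values (p <= 1e-4).

suppressMessages(library(crcscan))

params <- crc_params()
genes <- read_gtf_genes("results/synthetic/genes.gtf")
peaks <- read_narrowpeak("results/synthetic/peaks.narrowPeak")
signal <- read_bedgraph("results/synthetic/signal.bedGraph")
genome <- read_genome("results/synthetic/genome.fa")
pwms <- read_meme_motifs("results/synthetic/motifs.meme")
tfs <- readLines("results/synthetic/tf_list.txt")

kept <- exclude_promoter_peaks(peaks, genes, params$tss_window)
tab <- call_superenhancers(quantify(stitch(kept, params$stitch_distance),
                                    signal))
asg <- assign_genes(tab, genes, params$assign_window, restrict_to = tfs)

se <- tab$regions[tab$regions$is_super]
se <- se[se$region_id %in% asg$se_id]
windows <- extend_regions(se, params$extension,
                          stats::setNames(Biostrings::width(genome),
                                          names(genome)))
hits <- scan_regions(windows, genome, pwms, params)

hits_out <- hits
hits_out$score <- sprintf("%.4f", hits_out$score)
hits_out$pvalue <- sprintf("%.6g", hits_out$pvalue)
write.table(hits_out, "results/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(count_hits(hits, asg,
                       source_tfs = vapply(pwms, `[[`, "", "tf_symbol"),
                       target_tfs = se_associated_tfs(asg)),
            "results/counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Scanned %d extended SE regions x %d motifs: %d hits\n",
            length(windows), length(pwms), nrow(hits)))
cat("Wrote results/hits.tsv and results/counts.tsv\n")
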