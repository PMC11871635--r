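# End-to-end orchestration: peaks + signal + genes + genome + motifs ->
# stitched regions -> ranked super-enhancers -> gene assignment -> motif
# scanning over extended super-enhancers -> regulatory graph -> scored
# circuitries; plus validation against a synthetic truth file.

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      stop(sprintf("input file not found: %s", x), call. = FALSE)
    }
    reader(x)
  } else {
    x
  }
}

#' Run the complete CRC discovery pipeline
#'
#' Stages: promoter-peak exclusion, ROSE-style stitching, signal
#' quantification, hockey-stick super-enhancer calling, TSS-proximity gene
#' assignment (optionally restricted to a TF list), FIMO-style motif
#' scanning of the 500 bp-extended super-enhancer regions, regulatory-graph
#' construction, circuitry enumeration and occurrence-frequency scoring.
#' Every argument accepts either a parsed object or a file path.
#'
#' @param peaks Peak calls (`GRanges` or narrowPeak/BED path).
#' @param genes Gene models (`GRanges` or GTF path).
#' @param genome Genome sequence (`DNAStringSet` or FASTA path).
#' @param motifs Motifs (list of `"pwm"` or MEME-format path).
#' @param signal Optional signal track (`GRanges` or bedGraph path);
#'   without it, region signal falls back to summed peak signalValues.
#' @param control Optional control track for input subtraction.
#' @param tf_list Optional TF symbols (character vector or one-per-line
#'   file) restricting gene assignment to TF genes.
#' @param params A [crc_params()] object.
#' @param out_dir Optional output directory; when given, writes
#'   `regions.tsv`, `se_table.tsv`, `assignments.tsv`, `hits.tsv`,
#'   `counts.tsv`, `circuitries.tsv`, `edges.tsv`, `params.json` and
#'   `run.log`.
#' @param verbose Print stage progress.
#' @return A list of class `"crc_run"` with elements `regions`, `table`,
#'   `assignments`, `se_tfs`, `scan_windows`, `hits`, `counts`, `graph`,
#'   `circuitries`, `params`, `log`.
#' @export
run_crc_pipeline <- function(peaks, genes, genome, motifs,
                             signal = NULL, control = NULL, tf_list = NULL,
                             params = crc_params(), out_dir = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(params, "crc_params"))
  logl <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logl <<- c(logl, msg)
    if (verbose) message(msg)
  }
  peaks <- resolve_input(peaks, read_narrowpeak)
  genes <- resolve_input(genes, read_gtf_genes)
  genome <- resolve_input(genome, read_genome)
  motifs <- resolve_input(motifs, read_meme_motifs)
  signal <- if (is.null(signal)) NULL else resolve_input(signal, read_bedgraph)
  control <- if (is.null(control)) NULL
             else resolve_input(control, read_bedgraph)
  tf_list <- if (is.null(tf_list)) NULL
             else if (is.character(tf_list) && length(tf_list) == 1 &&
                      file.exists(tf_list)) readLines(tf_list) else tf_list

  say("peaks in: %d", length(peaks))
  kept <- exclude_promoter_peaks(peaks, genes, params$tss_window)
  say("peaks after promoter exclusion (+/- %g bp): %d",
      params$tss_window, length(kept))
  regions <- stitch(kept, params$stitch_distance)
  say("stitched regions (gap <= %g bp): %d",
      params$stitch_distance, length(regions))
  regions <- quantify(regions, signal = signal, control = control)
  table <- call_superenhancers(regions)
  say("super-enhancers: %d of %d (cutoff %.6g at rank %d)",
      sum(table$regions$is_super), length(regions),
      table$cutoff, table$cutoff_index)
  assignments <- assign_genes(table, genes, window = params$assign_window,
                              restrict_to = tf_list)
  se_tfs <- se_associated_tfs(assignments)
  say("SE-associated TFs (window %g bp): %d",
      params$assign_window, length(se_tfs))

  se <- table$regions[table$regions$is_super]
  se <- se[se$region_id %in% assignments$se_id]
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  windows <- extend_regions(se, params$extension, seqlens)
  hits <- scan_regions(windows, genome, motifs, params)
  say("motif hits over %d extended regions x %d motifs (p <= %g): %d",
      length(windows), length(motifs), params$pvalue_threshold, nrow(hits))
  motif_tfs <- vapply(motifs, function(p) p$tf_symbol, character(1))
  counts <- count_hits(hits, assignments, source_tfs = motif_tfs,
                       target_tfs = se_tfs)
  graph <- build_graph(counts, tfs = se_tfs, edge_min = params$edge_min)
  auto <- autoregulated_tfs(graph, params$self_threshold)
  say("autoregulated TFs (self count > %g): %d",
      params$self_threshold, length(auto))
  circ <- enumerate_circuitries(graph, min_size = params$min_size,
                                max_size = params$max_size,
                                self_threshold = params$self_threshold)
  scored <- score_circuitries(circ, maximal_only = params$maximal_only)
  say("circuitries: %d (top: %s)", nrow(scored),
      if (nrow(scored)) paste(top_circuitry(scored), collapse = ",")
      else "none")

  run <- structure(list(regions = regions, table = table,
                        assignments = assignments, se_tfs = se_tfs,
                        scan_windows = windows, hits = hits,
                        counts = counts, graph = graph,
                        circuitries = scored, params = params, log = logl),
                   class = "crc_run")
  if (!is.null(out_dir)) write_crc_run(run, out_dir)
  run
}

#' @export
print.crc_run <- function(x, ...) {
  cat("CRC pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write all tables of a pipeline run
#' @param run A `"crc_run"` object.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_crc_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_se_table(run$table, file.path(out_dir, "se_table.tsv"),
                 assignments = run$assignments)
  rg <- run$regions
  utils::write.table(
    data.frame(region_id = rg$region_id,
               chrom = as.character(GenomicRanges::seqnames(rg)),
               start = GenomicRanges::start(rg) - 1L,
               end = GenomicRanges::end(rg),
               n_constituents = rg$n_constituents,
               signal = fmt_num(rg$signal, 6)),
    file.path(out_dir, "regions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- run$hits
  hits$score <- fmt_num(hits$score, 4)
  hits$pvalue <- sprintf("%.6g", hits$pvalue)
  utils::write.table(hits, file.path(out_dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$counts, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report_crc(run$graph, run$circuitries, out_dir)
  pj <- run$params
  pj$max_size <- pj$max_size %||% NA
  writeLines(jsonlite::toJSON(unclass(pj), pretty = TRUE, auto_unbox = TRUE,
                              digits = 10),
             file.path(out_dir, "params.json"))
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Validate a pipeline run against a synthetic truth file
#'
#' Reports whether the top-ranked circuitry equals the planted core TF set,
#' recall/precision of super-enhancer calls against the planted clusters,
#' and a per-edge detection table over the planted core pairs.
#'
#' @param run A `"crc_run"` object (or a directory written by
#'   [write_crc_run()]).
#' @param truth A truth list from [read_truth()] (or the path to
#'   `truth.json`).
#' @return A list with `recovered` (logical), `top` (top circuitry
#'   members), `se_recall`, `se_precision`, `n_super`, `autoregulated`,
#'   `edge_detection` (data.frame over ordered core pairs).
#' @export
validate_against_truth <- function(run, truth) {
  truth <- if (is.character(truth)) read_truth(truth) else truth
  if (is.character(run)) {
    if (!file.exists(file.path(run, "se_table.tsv"))) {
      stop(sprintf("'%s' does not contain pipeline output", run),
           call. = FALSE)
    }
    se_df <- read_se_table(file.path(run, "se_table.tsv"))
    se_df <- se_df[se_df$is_super, , drop = FALSE]
    circ <- utils::read.delim(file.path(run, "circuitries.tsv"),
                              stringsAsFactors = FALSE)
    top <- if (nrow(circ)) strsplit(circ$members[1], ",")[[1]]
           else character(0)
    counts <- utils::read.delim(file.path(run, "counts.tsv"),
                                stringsAsFactors = FALSE)
    auto <- character(0) # not reconstructed from disk
  } else {
    se <- run$table$regions[run$table$regions$is_super]
    se_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(se)),
                        start = GenomicRanges::start(se) - 1L,
                        end = GenomicRanges::end(se))
    top <- top_circuitry(run$circuitries)
    counts <- run$counts
    auto <- autoregulated_tfs(run$graph, run$params$self_threshold)
  }
  core <- sort(truth$core_tfs)
  cl <- truth$clusters
  se_gr <- GenomicRanges::GRanges(se_df$chrom,
                                  IRanges::IRanges(se_df$start + 1L,
                                                   se_df$end))
  cl_gr <- GenomicRanges::GRanges(cl$chrom,
                                  IRanges::IRanges(cl$start + 1L, cl$end))
  core_hit <- GenomicRanges::countOverlaps(cl_gr[cl$is_core], se_gr) > 0
  se_in_planted <- GenomicRanges::countOverlaps(se_gr, cl_gr) > 0
  pairs <- expand.grid(source_tf = core, target_tf = core,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(counts$source_tf, counts$target_tf)
  cnt <- counts$count[match(paste(pairs$source_tf, pairs$target_tf), key)]
  cnt[is.na(cnt)] <- 0
  pairs$count <- cnt
  pairs$detected <- cnt >= 1
  list(recovered = setequal(top, core),
       top = top,
       se_recall = mean(core_hit),
       se_precision = if (length(se_gr)) mean(se_in_planted) else NA_real_,
       n_super = length(se_gr),
       autoregulated = auto,
       edge_detection = pairs)
}

#' Simulate a planted epigenome and run the recovery pipeline on it
#'
#' Convenience wrapper chaining [plant_epigenome()], [run_crc_pipeline()]
#' and [validate_against_truth()].
#'
#' @param config A [synthetic_config()].
#' @param dir Working directory for the generated files (a temporary
#'   directory by default, removed afterwards unless `keep = TRUE`).
#' @param keep Keep the generated files and pipeline output.
#' @param verbose Passed to [run_crc_pipeline()].
#' @return A list with `run`, `validation`, `truth` and (if kept) `dir`.
#' @export
simulate_and_recover <- function(config = synthetic_config(),
                                 dir = tempfile("crcsim"), keep = FALSE,
                                 verbose = FALSE) {
  sim <- plant_epigenome(config, dir)
  run <- run_crc_pipeline(
    peaks = sim$files$peaks, genes = sim$files$genes,
    genome = sim$files$genome, motifs = sim$files$motifs,
    signal = sim$files$signal, tf_list = readLines(sim$files$tf_list),
    params = config$scan,
    out_dir = if (keep) file.path(dir, "out") else NULL,
    verbose = verbose)
  val <- validate_against_truth(run, sim$truth)
  if (!keep) unlink(dir, recursive = TRUE)
  list(run = run, validation = val, truth = sim$truth,
       dir = if (keep) dir else NULL)
}

#' Hockey-stick plot of a ranked enhancer table
#'
#' Signal against ascending rank with the cutoff marked — the standard
#' visualisation of super-enhancer calling.
#'
#' @param table An `"enhancer_table"`.
#' @param path Optional file (pdf/png by extension); `NULL` draws to the
#'   active device.
#' @return Invisibly, `table`.
#' @export
plot_hockey <- function(table, path = NULL) {
  if (!is.null(path)) {
    if (grepl("\\.png$", path)) {
      grDevices::png(path, width = 900, height = 700, res = 130)
    } else {
      grDevices::pdf(path, width = 6, height = 5)
    }
    on.exit(grDevices::dev.off())
  }
  r <- table$regions
  graphics::plot(r$rank, r$signal, pch = 20, cex = 0.6,
                 col = ifelse(r$is_super, "firebrick", "grey40"),
                 xlab = "enhancer rank (ascending signal)",
                 ylab = "H3K27ac signal",
                 main = sprintf("%d super-enhancers above cutoff",
                                sum(r$is_super)))
  graphics::abline(h = table$cutoff, lty = 2)
  graphics::abline(v = table$cutoff_index, lty = 3)
  invisible(table)
}
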