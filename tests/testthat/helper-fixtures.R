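# Shared fixture builders. Everything is generated in code; no stored data.

# minimal SAM text for given record fields
sam_line <- function(qname, flag, rname, pos, cigar, seq) {
  paste(qname, flag, rname, pos, 255, cigar, "*", 0, 0, seq, "*", sep = "\t")
}

write_tiny_sam <- function(lines, header = "@HD\tVN:1.6") {
  path <- withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

# proper pair flags: read1 = 1+2+64 = 67, read2 = 1+2+128 = 131
FLAG_R1 <- 67
FLAG_R2 <- 131

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# build alignment_records directly
make_records <- function(qname, is_read1, reference, pos, cigar, seq,
                         proper = TRUE) {
  rec <- data.frame(
    query_name = qname, is_read1 = is_read1,
    is_proper_pair = rep_len(proper, length(qname)),
    reference_name = reference, position = as.integer(pos),
    cigar = cigar, sequence = seq, stringsAsFactors = FALSE
  )
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

make_pair <- function(qname, reference, pos1, pos2, cigar1, cigar2,
                      seq1, seq2, proper = TRUE) {
  make_records(rep(qname, 2), c(TRUE, FALSE), rep(reference, 2),
               c(pos1, pos2), c(cigar1, cigar2), c(seq1, seq2), proper)
}

toy_annotations <- function(lengths, mito = FALSE, spike = FALSE) {
  n <- length(lengths)
  data.frame(
    transcript_id = names(lengths) %||% sprintf("TX%03d", seq_len(n)),
    gene_id = sprintf("G%03d", seq_len(n)),
    gene_symbol = sprintf("G%03d", seq_len(n)),
    length = as.integer(lengths),
    biotype = "protein_coding",
    is_mitochondrial = rep_len(mito, n),
    is_spikein = rep_len(spike, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force oracles -----------------------------------------------------

# k-mer unique fraction by explicit dictionary tabulation
brute_kmer_fraction <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(0)
  kmers <- character(n - k + 1)
  for (i in seq_len(n - k + 1)) kmers[i] <- substr(seq, i, i + k - 1)
  counts <- list()
  for (km in kmers) counts[[km]] <- (counts[[km]] %||% 0) + 1
  hits <- 0
  for (km in kmers) if (counts[[km]] == 1) hits <- hits + 1
  hits / length(kmers)
}

# longest mapped stretch by explicit run scanning
brute_mapped_stretch <- function(ops) {
  best <- 0; run <- 0
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] %in% c("M", "=", "X")) run <- run + ops$len[i]
    else run <- 0
    best <- max(best, run)
  }
  best
}

# per-base interval stabbing count
brute_depth <- function(starts, ends, L) {
  depth <- integer(L)
  for (i in seq_along(starts)) {
    lo <- max(1, starts[i]); hi <- min(L, ends[i])
    if (lo <= hi) depth[lo:hi] <- depth[lo:hi] + 1L
  }
  depth
}

# BH from its defining formula: p_adj(i) = min over j with p_(j) >= p_(i)
# of m * p_(j) / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(m * ranked[i:m] / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# GSEA running-sum enrichment score, literal loop; positive extreme wins
# magnitude ties (same convention as the implementation)
brute_gsea_es <- function(ranked_stats, in_set) {
  nr <- sum(abs(ranked_stats[in_set]))
  n_miss <- sum(!in_set)
  if (n_miss == 0 || nr == 0) return(0)
  run <- 0; max_pos <- -Inf; min_neg <- Inf
  for (i in seq_along(ranked_stats)) {
    run <- run + if (in_set[i]) abs(ranked_stats[[i]]) / nr else -1 / n_miss
    if (run > max_pos) max_pos <- run
    if (run < min_neg) min_neg <- run
  }
  if (max_pos >= -min_neg - 1e-12) max_pos else min_neg
}
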