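# ---- CIGAR helpers -----------------------------------------------------------

#' Parse a CIGAR string into an operation table
#'
#' @param cigar CIGAR string, e.g. `"50M2I48M"`, or `"*"`.
#' @return A data.frame with columns `op` (character, one of
#'   M, I, D, N, S, H, P, =, X) and `len` (integer). `"*"` yields zero rows.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0 || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  data.frame(
    op  = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
    stringsAsFactors = FALSE
  )
}

#' Reference-consuming length of a CIGAR string
#'
#' Sum of lengths of M, D, N, = and X operations: the number of reference
#' (transcript) bases the alignment spans.
#'
#' @param cigar CIGAR string.
#' @return Integer span in nt.
#' @export
cigar_reference_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# query-consuming length (M, I, S, =, X)
cigar_query_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

# ---- SAM ---------------------------------------------------------------------

# SAM flag bits we model
FLAG_PAIRED      <- 1L
FLAG_PROPER_PAIR <- 2L
FLAG_UNMAPPED    <- 4L
FLAG_READ1       <- 64L
FLAG_READ2       <- 128L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read alignment records from a SAM text file
#'
#' Parses transcriptome-coordinate alignments into a record table. Header
#' lines are skipped; unmapped records (flag 0x4 or reference `"*"`) are
#' dropped. Only the fields the pipeline uses are retained: query name, pair
#' flags, reference, 1-based position, CIGAR and sequence.
#'
#' @param path Path to a SAM file (header optional).
#' @return A data.frame of class `alignment_records` with columns
#'   `query_name`, `is_read1`, `is_proper_pair`, `reference_name`,
#'   `position`, `cigar`, `sequence`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignment_records())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1],
         ": fewer than 11 fields")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag_chr <- get(2L)
  flag <- suppressWarnings(as.integer(flag_chr))
  if (anyNA(flag)) {
    stop("malformed SAM flag field at line ", which(is.na(flag))[1])
  }
  cigar <- get(6L)
  bad <- !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", cigar)
  if (any(bad)) {
    stop("malformed CIGAR at line ", which(bad)[1], ": ", cigar[which(bad)[1]])
  }
  rec <- data.frame(
    query_name     = get(1L),
    is_read1       = has_flag(flag, FLAG_READ1),
    is_proper_pair = has_flag(flag, FLAG_PROPER_PAIR),
    reference_name = get(3L),
    position       = as.integer(get(4L)),
    cigar          = cigar,
    sequence       = get(10L),
    stringsAsFactors = FALSE
  )
  mapped <- !has_flag(flag, FLAG_UNMAPPED) & rec$reference_name != "*"
  rec <- rec[mapped, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

empty_alignment_records <- function() {
  rec <- data.frame(
    query_name = character(0), is_read1 = logical(0),
    is_proper_pair = logical(0), reference_name = character(0),
    position = integer(0), cigar = character(0), sequence = character(0),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("alignment_records", "data.frame")
  rec
}

#' Write alignment records to a SAM text file
#'
#' Inverse of [read_sam()] for the retained fields. Flags are reconstructed
#' from the pair columns (0x1 always set, 0x2 for proper pairs, 0x40/0x80
#' for mate identity); all other SAM columns are filled with their
#' unavailable-value placeholders.
#'
#' @param records An `alignment_records` data.frame.
#' @param path Output path.
#' @param reference_lengths Optional named integer vector of transcript
#'   lengths used to emit `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, reference_lengths = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(reference_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d",
                       names(reference_lengths),
                       as.integer(reference_lengths)), con)
  }
  if (nrow(records) > 0) {
    flag <- FLAG_PAIRED +
      ifelse(records$is_proper_pair, FLAG_PROPER_PAIR, 0L) +
      ifelse(records$is_read1, FLAG_READ1, FLAG_READ2)
    writeLines(paste(records$query_name, flag, records$reference_name,
                     records$position, 255L, records$cigar,
                     "*", 0L, 0L, records$sequence, "*",
                     sep = "\t"), con)
  }
  invisible(path)
}

# ---- GTF ---------------------------------------------------------------------

#' Read transcript annotations from a GTF file
#'
#' Imports exon features and aggregates them per transcript: the transcript
#' length is the summed exon length (1-based inclusive intervals). A
#' transcript is flagged mitochondrial when its seqname is in `mito_seqnames`
#' and spike-in when its transcript id is in `spikein_ids`.
#'
#' @param path GTF file path.
#' @param mito_seqnames Seqnames treated as the mitochondrial genome.
#' @param spikein_ids Transcript ids of spike-in sequences.
#' @return A data.frame with columns `transcript_id`, `gene_id`,
#'   `gene_symbol`, `length`, `biotype`, `is_mitochondrial`, `is_spikein`.
#' @export
read_gtf <- function(path, mito_seqnames = c("MT", "chrM"),
                     spikein_ids = character(0)) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tx_ids_all <- unique(meta$transcript_id[!is.na(meta$transcript_id)])
  ex <- gr[type == "exon" & !is.na(meta$transcript_id)]
  exm <- S4Vectors::mcols(ex)
  txid <- as.character(exm$transcript_id)
  if (length(txid)) {
    seqn <- as.character(GenomicRanges::seqnames(ex))
    n_seq <- tapply(seqn, txid, function(s) length(unique(s)))
    if (any(n_seq > 1)) {
      stop("duplicated transcript_id with conflicting coordinates: ",
           names(n_seq)[n_seq > 1][1])
    }
    len <- tapply(GenomicRanges::width(ex), txid, sum)
    first <- !duplicated(txid)
    ann <- data.frame(
      transcript_id = txid[first],
      gene_id = as.character(exm$gene_id[first]),
      gene_symbol = if (!is.null(exm$gene_name))
        as.character(exm$gene_name[first]) else as.character(exm$gene_id[first]),
      length = as.integer(len[txid[first]]),
      biotype = if (!is.null(exm$gene_biotype))
        as.character(exm$gene_biotype[first]) else NA_character_,
      is_mitochondrial = seqn[first] %in% mito_seqnames,
      stringsAsFactors = FALSE
    )
  } else {
    ann <- data.frame(
      transcript_id = character(0), gene_id = character(0),
      gene_symbol = character(0), length = integer(0),
      biotype = character(0), is_mitochondrial = logical(0),
      stringsAsFactors = FALSE
    )
  }
  exonless <- setdiff(tx_ids_all, ann$transcript_id)
  if (length(exonless) > 0) {
    warning(length(exonless), " transcript(s) without exon features dropped: ",
            paste(utils::head(exonless, 5), collapse = ", "))
  }
  ann$is_spikein <- ann$transcript_id %in% spikein_ids
  rownames(ann) <- NULL
  ann
}

# ---- quant tables ------------------------------------------------------------

#' Read a transcript quantification table
#'
#' Reads a tab-separated quantification table in the quant.sf dialect
#' (columns `Name`, `Length`, `TPM`, `NumReads` by default; names
#' configurable).
#'
#' @param path TSV path with header.
#' @param columns Named character vector mapping the canonical fields
#'   `transcript_id`, `length`, `tpm`, `reads` to the file's column names.
#' @return Data.frame with columns `transcript_id`, `length`, `tpm`, `reads`.
#' @export
read_quant_table <- function(path,
                             columns = c(transcript_id = "Name",
                                         length = "Length",
                                         tpm = "TPM",
                                         reads = "NumReads")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(tab))
  if (length(missing) > 0) {
    stop("quant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    transcript_id = as.character(tab[[columns[["transcript_id"]]]]),
    length = as.integer(tab[[columns[["length"]]]]),
    tpm = as.numeric(tab[[columns[["tpm"]]]]),
    reads = as.numeric(tab[[columns[["reads"]]]]),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0 && (any(out$tpm < 0) || any(out$reads < 0))) {
    stop("quant table contains negative TPM or read counts")
  }
  out
}

# ---- GMT ---------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, then member ids, tab-separated.
#' Members are deduplicated within a set; duplicated set names are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique member ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("malformed GMT line (need at least name and description)")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name in GMT: ", nm[duplicated(nm)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  sets
}

# ---- count matrices ----------------------------------------------------------

#' Construct a count matrix with sample metadata
#'
#' The shared tabular container for the pipeline: a non-negative
#' features-by-samples matrix plus per-sample metadata (compartment,
#' condition, lineage, time, replicate) and the unit of the values.
#'
#' @param values Numeric matrix, features in rows, samples in columns;
#'   dimnames required.
#' @param sample_meta Data.frame with one row per sample (matched to columns
#'   of `values`); recognised columns: `compartment`
#'   (`"supernatant"`/`"lysate"`), `condition`, `lineage`, `time_days`,
#'   `replicate`.
#' @param unit One of `"counts"`, `"CPM"`, `"TPM"`.
#' @return An object of class `count_matrix`: a list with elements `values`,
#'   `sample_meta`, `unit`.
#' @export
count_matrix <- function(values, sample_meta = NULL, unit = "counts") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("count_matrix values need feature and sample dimnames")
  }
  if (any(values < 0)) stop("count_matrix values must be non-negative")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(row.names = colnames(values))
  }
  if (nrow(sample_meta) != ncol(values)) {
    stop("sample_meta rows must match the number of samples")
  }
  rownames(sample_meta) <- colnames(values)
  structure(list(values = values, sample_meta = sample_meta, unit = unit),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (ncol(x$sample_meta) > 0) {
    cat("sample metadata:", paste(names(x$sample_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a features-by-samples count matrix from TSV
#'
#' First column holds feature ids; remaining columns are samples.
#'
#' @param path TSV path.
#' @param unit Value unit to record.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, unit = "counts") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  count_matrix(values, unit = unit)
}

#' Write a count matrix to TSV
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  tab <- data.frame(feature_id = rownames(cm$values), cm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
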