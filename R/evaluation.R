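# Classifier evaluation (ground truth, ROC/PR), sliding-window differential
# expression, preranked gene set enrichment, time-to-peak ordering, and
# contraction-frequency estimation from image-intensity traces.

#' Build ground-truth labels from interval-null Wald results
#'
#' Positives: genes significant under the `greaterAbs` test (|log2 FC| > 1)
#' at the given FDR; negatives: significant under `lessAbs` (|log2 FC| < 1).
#' Everything else is unlabeled and excluded from curves.
#'
#' @param greater_abs,less_abs Data.frames from [nb_wald_de()] with
#'   `gene_id` and `p_adjusted` (same gene universe).
#' @param fdr FDR threshold.
#' @return List with `positives`, `negatives`, `unlabeled` (gene ids) and
#'   `counts`.
#' @export
build_ground_truth <- function(greater_abs, less_abs, fdr = 0.05) {
  stopifnot(identical(greater_abs$gene_id, less_abs$gene_id))
  pos <- greater_abs$gene_id[!is.na(greater_abs$p_adjusted) &
                               greater_abs$p_adjusted < fdr]
  neg <- less_abs$gene_id[!is.na(less_abs$p_adjusted) &
                            less_abs$p_adjusted < fdr]
  both <- intersect(pos, neg)
  pos <- setdiff(pos, both); neg <- setdiff(neg, both)
  unlabeled <- setdiff(greater_abs$gene_id, c(pos, neg))
  list(positives = pos, negatives = neg, unlabeled = unlabeled,
       counts = c(positives = length(pos), negatives = length(neg),
                  unlabeled = length(unlabeled)))
}

#' ROC and precision-recall curves from per-gene scores
#'
#' Scores follow the convention "larger = more positive" when
#' `smaller_is_positive = FALSE`; adjusted p-values used as prediction
#' scores should be passed with `smaller_is_positive = TRUE` (they are
#' negated internally). Curves sweep all unique score thresholds plus the
#' two degenerate endpoints; AUCs are trapezoidal. The random-classifier
#' baseline precision equals the positive prevalence.
#'
#' @param labels A list from [build_ground_truth()] (or with elements
#'   `positives` and `negatives`).
#' @param scores Named per-gene scores covering all labeled genes.
#' @param smaller_is_positive Set when smaller scores indicate positives.
#' @return List with `roc` (data.frame threshold/fpr/tpr), `pr` (data.frame
#'   threshold/recall/precision), `roc_auc`, `pr_auc`, `prevalence`.
#' @export
roc_pr_curves <- function(labels, scores, smaller_is_positive = FALSE) {
  ids <- c(labels$positives, labels$negatives)
  if (length(labels$positives) == 0 || length(labels$negatives) == 0) {
    stop("need at least one positive and one negative label")
  }
  if (!all(ids %in% names(scores))) stop("scores missing for labeled genes")
  s <- scores[ids]
  if (smaller_is_positive) s <- -s
  y <- c(rep(TRUE, length(labels$positives)),
         rep(FALSE, length(labels$negatives)))
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  P <- sum(y); N <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  # one operating point per unique score (take the last index of each run)
  last <- !duplicated(s, fromLast = TRUE)
  thr <- s[last]; tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  precision <- c(1, tp / (tp + fp))
  recall <- tpr
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pr_auc <- sum(diff(recall) * (utils::head(precision, -1) +
                                  utils::tail(precision, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = c(Inf, thr), recall = recall,
                       precision = precision),
       roc_auc = roc_auc, pr_auc = pr_auc,
       prevalence = P / (P + N))
}

#' Sliding-window differential expression along a time course
#'
#' For each anchor day t, samples in days `[t - 2, t - 1]` (reference) are
#' compared against days `[t, t + 1]` (current) with a negative-binomial
#' Wald test; windows advance with a one-day stride. For T consecutive
#' daily time points this yields T - 3 comparisons. Non-integer sampling
#' times are assigned to days by flooring.
#'
#' @param counts A [count_matrix()] with `time_days` metadata, or a matrix
#'   plus `times`.
#' @param times Per-sample times (days); defaults to the metadata.
#' @param bin_days Window width in days.
#' @return List of per-window results: each has `anchor_day`, `reference_days`,
#'   `current_days`, and `de` (data.frame from [nb_wald_de()]). Windows with
#'   fewer than 2 samples on either side are skipped with a warning.
#' @export
sliding_window_de <- function(counts, times = NULL, bin_days = 2) {
  vals <- values_of(counts)
  if (is.null(times) && inherits(counts, "count_matrix")) {
    times <- counts$sample_meta$time_days
  }
  stopifnot(length(times) == ncol(vals))
  day <- floor(times)
  days <- sort(unique(day))
  anchors <- seq(min(days) + bin_days, max(days) - (bin_days - 1))
  out <- list()
  for (t in anchors) {
    ref_days <- (t - bin_days):(t - 1)
    cur_days <- t:(t + bin_days - 1)
    ref_idx <- which(day %in% ref_days)
    cur_idx <- which(day %in% cur_days)
    if (length(ref_idx) < 2 || length(cur_idx) < 2) {
      warning("window at day ", t, " skipped: fewer than 2 samples per side")
      next
    }
    sub <- vals[, c(ref_idx, cur_idx), drop = FALSE]
    cond <- rep(c("ref", "cur"), c(length(ref_idx), length(cur_idx)))
    de <- nb_wald_de(sub, cond, ref = "ref")
    out[[length(out) + 1]] <- list(anchor_day = t,
                                   reference_days = ref_days,
                                   current_days = cur_days, de = de)
  }
  out
}

# running-sum enrichment score with weight |stat|^1 on a ranked list.
# ES is the extreme deviation; when the positive and negative extremes tie
# in magnitude (within float tolerance) the positive one is reported.
gsea_es <- function(ranked_stats, in_set) {
  nr <- sum(abs(ranked_stats[in_set]))
  n_miss <- sum(!in_set)
  if (n_miss == 0 || nr == 0) return(0)
  step <- ifelse(in_set, abs(ranked_stats) / nr, -1 / n_miss)
  run <- cumsum(step)
  max_pos <- max(run)
  min_neg <- min(run)
  if (max_pos >= -min_neg - 1e-12) unname(max_pos) else unname(min_neg)
}

#' Preranked gene set enrichment analysis
#'
#' Genes are ranked by the supplied statistic (descending); the enrichment
#' score is the maximal deviation of the weighted running sum
#' (weight = |statistic|). Significance is by gene-label permutation:
#' for each set, random gene sets of the same size are drawn, the p-value
#' is the frequency of same-sign null scores at least as extreme, and
#' NES = ES / mean(|null ES| of matching sign). P-values are BH adjusted
#' across sets and results sorted by adjusted p.
#'
#' @param stats_by_gene Named per-gene ranking statistics (finite).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param n_permutations Permutations per set.
#' @param seed Integer seed for the permutation null.
#' @param min_size Sets with fewer in-universe members are skipped with a
#'   warning.
#' @return Data.frame with `set`, `size`, `es`, `nes`, `p_value`,
#'   `p_adjusted`, `leading_edge` (comma-separated gene ids).
#' @export
preranked_gsea <- function(stats_by_gene, gene_sets, n_permutations = 1000,
                           seed = 1L, min_size = 3) {
  stopifnot(all(is.finite(stats_by_gene)))
  ord <- order(stats_by_gene, decreasing = TRUE)
  ranked <- stats_by_gene[ord]
  genes <- names(ranked)
  sets <- lapply(gene_sets, intersect, y = genes)
  small <- lengths(sets) < min_size
  if (any(small)) {
    warning(sum(small), " gene set(s) with fewer than ", min_size,
            " members in the ranked universe skipped")
    sets <- sets[!small]
  }
  if (length(sets) == 0) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), leading_edge = character(0)))
  }
  res <- with_seed(seed, {
    lapply(names(sets), function(nm) {
      members <- sets[[nm]]
      in_set <- genes %in% members
      es <- gsea_es(ranked, in_set)
      null_es <- vapply(seq_len(n_permutations), function(i) {
        idx <- sample(length(genes), length(members))
        hit <- logical(length(genes)); hit[idx] <- TRUE
        gsea_es(ranked, hit)
      }, numeric(1))
      same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      p <- (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
      nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
        es / mean(abs(same_sign))
      } else NA_real_
      # leading edge: hits up to the running-sum extremum
      nr <- sum(abs(ranked[in_set]))
      step <- ifelse(in_set, abs(ranked) / max(nr, .Machine$double.eps),
                     -1 / max(sum(!in_set), 1))
      run <- cumsum(step)
      peak <- if (es >= 0) which.max(run) else which.min(run)
      le <- if (es >= 0) genes[seq_len(peak)][in_set[seq_len(peak)]] else {
        genes[peak:length(genes)][in_set[peak:length(genes)]]
      }
      data.frame(set = nm, size = length(members), es = es, nes = nes,
                 p_value = p, p_adjusted = NA_real_,
                 leading_edge = paste(le, collapse = ","),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_adjusted, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Order genes by time to peak expression
#'
#' Expression is log2-transformed with a pseudocount and row-centered; each
#' gene's time to peak is the time of its maximum. Genes are sorted by it
#' ascending, ties broken by gene id.
#'
#' @param means Genes x time points matrix of mean expression; column names
#'   or `times` give the time values.
#' @param times Time values per column.
#' @param pseudocount Added before the log transform.
#' @return List with `matrix` (row-centered log2 values in peak order),
#'   `time_to_peak` (named vector, same order).
#' @export
time_to_peak_ordering <- function(means, times = NULL, pseudocount = 1) {
  means <- as.matrix(means)
  if (is.null(times)) times <- as.numeric(colnames(means))
  stopifnot(length(times) == ncol(means), !anyNA(times))
  lg <- log2(means + pseudocount)
  lg <- lg - rowMeans(lg)
  peak <- times[apply(lg, 1, which.max)]
  ord <- order(peak, rownames(means), method = "radix")
  list(matrix = lg[ord, , drop = FALSE],
       time_to_peak = stats::setNames(peak[ord], rownames(means)[ord]))
}

#' Contraction frequency from an image-intensity trace
#'
#' Local maxima with prominence above `prominence_sd` times the trace
#' standard deviation and separated by at least `min_distance_s` are taken
#' as contraction peaks; the frequency is (number of peaks - 1) divided by
#' the time between the first and last peak.
#'
#' @param trace Per-frame mean image intensity.
#' @param fps Frames per second.
#' @param min_distance_s Minimum peak separation (refractory period), s.
#' @param prominence_sd Prominence threshold in units of the trace sd.
#' @return List with `frequency_hz` (`NA` when fewer than 2 peaks),
#'   `peak_frames`, `n_peaks`.
#' @export
contraction_frequency <- function(trace, fps, min_distance_s = 0.3,
                                  prominence_sd = 0.5) {
  stopifnot(length(trace) >= 2 * fps)
  n <- length(trace)
  s <- stats::sd(trace)
  if (s == 0) return(list(frequency_hz = NA_real_, peak_frames = integer(0),
                          n_peaks = 0L))
  is_max <- c(FALSE, diff(trace) > 0) & c(trace[-n] > trace[-1], FALSE)
  cand <- which(is_max)
  # prominence: height above the higher of the two flanking minima
  prom <- vapply(cand, function(i) {
    left <- if (i > 1) min(trace[max(1, i - round(2 * fps)):i]) else trace[i]
    right <- min(trace[i:min(n, i + round(2 * fps))])
    trace[i] - max(left, right)
  }, numeric(1))
  cand <- cand[prom >= prominence_sd * s]
  # enforce the refractory distance, keeping the higher peak
  min_gap <- round(min_distance_s * fps)
  keep <- integer(0)
  for (i in cand[order(trace[cand], decreasing = TRUE)]) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2) {
    return(list(frequency_hz = NA_real_, peak_frames = keep,
                n_peaks = length(keep)))
  }
  span_s <- (keep[length(keep)] - keep[1]) / fps
  list(frequency_hz = (length(keep) - 1) / span_s,
       peak_frames = keep, n_peaks = length(keep))
}
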