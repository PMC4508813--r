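# Recall / precision / boundary-error scoring of calls against a truth
# set, by reciprocal-overlap matching within element kinds.

#' Score element calls against a truth set
#'
#' A call matches a truth entry of the same kind on the same sequence when
#' their reciprocal overlap is at least `min_reciprocal` (both
#' overlap/length fractions). Matches are assigned greedily by decreasing
#' overlap, one-to-one. Recall is matched truth / all truth, precision is
#' matching calls / all calls (reported as 1 with a warning when there are
#' no calls), and the boundary error of a match is the mean of its
#' absolute start and end differences.
#'
#' @param calls data frame with seqid, start, end, kind.
#' @param truth data frame with seqid, start, end, kind.
#' @param min_reciprocal reciprocal-overlap threshold (default 0.8).
#' @param by_kind also return per-kind rows (default TRUE).
#' @return data frame with columns kind (`"all"` plus per-kind rows),
#'   n_truth, n_calls, n_matched, recall, precision, boundary_error.
#' @export
score_calls <- function(calls, truth, min_reciprocal = 0.8,
                        by_kind = TRUE) {
  stopifnot(all(c("seqid", "start", "end", "kind") %in% names(truth)))
  if (nrow(calls) > 0L) {
    stopifnot(all(c("seqid", "start", "end", "kind") %in% names(calls)))
    if (!all(calls$seqid %in% truth$seqid))
      stop("score_calls: calls reference sequence id(s) absent from truth")
  }
  pairs <- NULL
  if (nrow(calls) > 0L && nrow(truth) > 0L) {
    qr <- GenomicRanges::GRanges(calls$seqid,
                                 IRanges::IRanges(calls$start, calls$end))
    sr <- GenomicRanges::GRanges(truth$seqid,
                                 IRanges::IRanges(truth$start, truth$end))
    ov <- GenomicRanges::findOverlaps(qr, sr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh) > 0L) {
      inter <- IRanges::width(IRanges::pintersect(
        IRanges::IRanges(calls$start[qh], calls$end[qh]),
        IRanges::IRanges(truth$start[sh], truth$end[sh])))
      wq <- calls$end[qh] - calls$start[qh] + 1L
      ws <- truth$end[sh] - truth$start[sh] + 1L
      rec <- pmin(inter / wq, inter / ws)
      same_kind <- calls$kind[qh] == truth$kind[sh]
      keep <- rec >= min_reciprocal & same_kind
      pairs <- data.frame(call = qh[keep], truth = sh[keep],
                          overlap = rec[keep])
    }
  }
  # Greedy one-to-one matching by decreasing reciprocal overlap.
  matched_call <- integer(0); matched_truth <- integer(0)
  berr <- numeric(0)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    pairs <- pairs[order(-pairs$overlap), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      if (pairs$call[i] %in% matched_call ||
          pairs$truth[i] %in% matched_truth) next
      matched_call <- c(matched_call, pairs$call[i])
      matched_truth <- c(matched_truth, pairs$truth[i])
      berr <- c(berr,
                (abs(calls$start[pairs$call[i]] -
                       truth$start[pairs$truth[i]]) +
                 abs(calls$end[pairs$call[i]] -
                       truth$end[pairs$truth[i]])) / 2)
    }
  }
  one_row <- function(kind, t_idx, c_idx) {
    nm <- sum(matched_truth %in% t_idx)
    n_t <- length(t_idx); n_c <- length(c_idx)
    recall <- if (n_t == 0L) NA_real_ else nm / n_t
    precision <- if (n_c == 0L) {
      warning("score_calls: no calls for kind '", kind,
              "'; precision reported as 1")
      1
    } else sum(matched_call %in% c_idx) / n_c
    be <- if (nm == 0L) NA_real_ else
      mean(berr[matched_truth %in% t_idx])
    data.frame(kind = kind, n_truth = n_t, n_calls = n_c, n_matched = nm,
               recall = recall, precision = precision, boundary_error = be,
               stringsAsFactors = FALSE)
  }
  rows <- list(one_row("all", seq_len(nrow(truth)), seq_len(nrow(calls))))
  if (by_kind) {
    for (k in sort(unique(truth$kind))) {
      rows[[length(rows) + 1L]] <-
        one_row(k, which(truth$kind == k), which(calls$kind == k))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
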