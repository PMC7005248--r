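# Alignment preprocessing: one best hit per read, insert-size window on
# proper pairs, and base-quality outlier removal. Filter order is fixed:
# best-hit -> insert-size -> base-quality; the quality summary is computed
# over the alignments remaining after the insert filter.

#' Keep the single best alignment per read end
#'
#' For every (read_id, mate) with at least one record, keeps the record with
#' maximal mapping quality. Ties are broken by (contig_id, start)
#' lexicographically, then input order, so the result is deterministic.
#'
#' @param records alignment records (see [parse_sam_records()]).
#' @return the retained records, in input order.
#' @export
select_best_alignments <- function(records) {
  if (!nrow(records)) return(records)
  key <- paste(records$read_id, records$mate, sep = "\r")
  ord <- order(key, -records$mapq, records$contig_id, records$start,
               seq_len(nrow(records)))
  best <- ord[!duplicated(key[ord])]
  records[sort(best), , drop = FALSE]
}

# proper pairs: both mates mapped to the same contig, opposite orientation,
# left mate forward. Returns a data.frame with row indices of both mates and
# the outer distance (rightmost aligned base of the right mate, exclusive,
# minus leftmost base of the left mate).
proper_pairs <- function(records) {
  if (!nrow(records)) {
    return(data.frame(i1 = integer(0), i2 = integer(0), outer = numeric(0)))
  }
  idx <- seq_len(nrow(records))
  m1 <- records$mate == 1L
  r1 <- records[m1, , drop = FALSE]; i1 <- idx[m1]
  r2 <- records[!m1, , drop = FALSE]; i2 <- idx[!m1]
  j <- match(r1$read_id, r2$read_id)
  ok <- !is.na(j)
  r1 <- r1[ok, , drop = FALSE]; i1 <- i1[ok]; j <- j[ok]
  same <- r1$contig_id == r2$contig_id[j] &
    r1$is_reverse != r2$is_reverse[j]
  r1 <- r1[same, , drop = FALSE]; i1 <- i1[same]; j <- j[same]
  if (!nrow(r1)) {
    return(data.frame(i1 = integer(0), i2 = integer(0), outer = numeric(0)))
  }
  s1 <- r1$start; e1 <- r1$start + r1$ref_span
  s2 <- r2$start[j]; e2 <- r2$start[j] + r2$ref_span[j]
  left_first <- s1 <= s2
  # left mate must be on the forward strand
  fr_ok <- ifelse(left_first, !r1$is_reverse, !r2$is_reverse[j])
  outer <- ifelse(left_first, e2 - s1, e1 - s2)
  keep <- fr_ok & outer > 0
  data.frame(i1 = i1[keep], i2 = i2[j[keep]], outer = outer[keep])
}

#' Fit the insert-size model
#'
#' Outer distances of proper pairs are modeled as normal; returns the sample
#' mean and sample standard deviation.
#'
#' @param records alignment records after best-hit selection.
#' @return list with `mu_is`, `sigma_is`, and `n_pairs`.
#' @export
fit_insert_size_model <- function(records) {
  pp <- proper_pairs(records)
  if (nrow(pp) < 2L) {
    stop("insufficient data: need at least 2 proper pairs to fit the insert-size model")
  }
  list(mu_is = mean(pp$outer), sigma_is = stats::sd(pp$outer), n_pairs = nrow(pp))
}

#' Filter alignments by insert size
#'
#' Proper pairs whose outer distance falls outside
#' [mu - k*sigma, mu + k*sigma] are removed (both mates). Alignments that are
#' not part of a proper pair are exempt and retained.
#'
#' @param records alignment records.
#' @param model insert-size model from [fit_insert_size_model()].
#' @param sigma_mult window half-width in standard deviations (default 3).
#' @return retained records.
#' @export
filter_pairs_by_insert <- function(records, model, sigma_mult = 3) {
  pp <- proper_pairs(records)
  if (!nrow(pp)) return(records)
  lo <- model$mu_is - sigma_mult * model$sigma_is
  hi <- model$mu_is + sigma_mult * model$sigma_is
  bad <- pp$outer < lo | pp$outer > hi
  drop <- c(pp$i1[bad], pp$i2[bad])
  if (!length(drop)) return(records)
  records[-drop, , drop = FALSE]
}

#' Filter alignments by mean base quality
#'
#' Computes Q_i (mean base quality per alignment), then the mean m_q and
#' standard deviation sigma_ra of the Q_i over all records, and removes
#' records with Q_i < m_q - k*sigma_ra.
#'
#' @param records alignment records carrying `mean_bq`.
#' @param sigma_mult threshold multiplier (default 3).
#' @return retained records.
#' @export
filter_by_base_quality <- function(records, sigma_mult = 3) {
  if (!nrow(records)) return(records)
  q <- records$mean_bq
  if (all(is.na(q))) return(records)
  m_q <- mean(q, na.rm = TRUE)
  sigma_ra <- stats::sd(q, na.rm = TRUE)
  if (is.na(sigma_ra)) sigma_ra <- 0
  keep <- is.na(q) | q >= m_q - sigma_mult * sigma_ra
  records[keep, , drop = FALSE]
}

#' Summary of per-alignment mean base qualities
#' @param records alignment records.
#' @return list with `m_q` and `sigma_ra`.
#' @export
quality_summary <- function(records) {
  q <- records$mean_bq
  list(m_q = mean(q, na.rm = TRUE),
       sigma_ra = if (sum(!is.na(q)) > 1) stats::sd(q, na.rm = TRUE) else 0)
}

#' Run the full preprocessing chain
#'
#' Best-hit selection, then the insert-size window, then base-quality
#' outlier removal.
#'
#' @param records raw alignment records.
#' @param insert_sigma_mult insert window width in sigmas (default 3).
#' @param quality_sigma_mult quality threshold in sigmas (default 3).
#' @return list with `records` (retained alignments), `insert_model`
#'   (or NULL when fewer than 2 proper pairs exist), and `quality`.
#' @export
preprocess_alignments <- function(records, insert_sigma_mult = 3,
                                  quality_sigma_mult = 3) {
  records <- select_best_alignments(records)
  model <- tryCatch(fit_insert_size_model(records), error = function(e) NULL)
  if (!is.null(model)) {
    records <- filter_pairs_by_insert(records, model, insert_sigma_mult)
  }
  qs <- quality_summary(records)
  records <- filter_by_base_quality(records, quality_sigma_mult)
  list(records = records, insert_model = model, quality = qs)
}
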