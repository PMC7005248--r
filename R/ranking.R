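# Assembly ranking. Each input assembly is scored from its read alignments:
# a per-position match/error profile (CIGAR characters voted +1/-1, with the
# M ambiguity resolved by comparing each read's MAPQ to the file mean), a
# per-read coverage-deviation flag, and the combined score
# (sum_q - sum_RC) / N over the set's N contigs.

#' Mean mapping quality of a set of alignments
#' @param records alignment records.
#' @return arithmetic mean of MAPQ.
#' @export
mean_mapping_score <- function(records) {
  if (!nrow(records)) stop("cannot compute a mean mapping score of zero alignments")
  mean(records$mapq)
}

#' Per-position match/error profile of one contig
#'
#' Each alignment votes on the reference positions it touches: match runs
#' (M with MAPQ >= the file mean, or =) vote +1; mismatch runs (M with low
#' MAPQ, or X), deletions, and insertions (charged to the preceding
#' reference position) vote -1. Votes are summed per position and clamped to
#' sign: +1, -1, or 0 where uncovered or exactly balanced.
#'
#' @param contig_id contig to profile.
#' @param contig_length its length.
#' @param records alignment records on that contig.
#' @param mean_mapq mean mapping score of the whole alignment file.
#' @return integer vector q of length `contig_length` with values in -1,0,+1.
#' @export
position_quality_profile <- function(contig_id, contig_length, records,
                                     mean_mapq) {
  records <- records[records$contig_id == contig_id, , drop = FALSE]
  if (any(records$start < 0L | records$start + records$ref_span > contig_length)) {
    stop("alignment outside the bounds of contig ", contig_id)
  }
  L <- contig_length
  if (!nrow(records)) return(integer(L))
  m_ok <- records$mapq >= mean_mapq
  # vectorize over unique CIGAR strings: each contributes a fixed pattern of
  # reference intervals relative to the alignment start
  uq <- unique(records$cigar)
  S <- list(); E <- list(); W <- list(); P <- list()
  for (u in uq) {
    cp <- parse_cigar(u)
    ref <- 0L
    rs <- integer(0); re <- integer(0); ty <- character(0); ip <- integer(0)
    for (i in seq_len(nrow(cp))) {
      op <- cp$op[i]; len <- cp$len[i]
      if (op %in% c("M", "=", "X", "D")) {
        rs <- c(rs, ref); re <- c(re, ref + len); ty <- c(ty, op)
        ref <- ref + len
      } else if (op == "I") {
        ip <- c(ip, ref)  # charge preceding reference position
      }
    }
    idx <- which(records$cigar == u)
    if (length(rs)) {
      n <- length(idx); k <- length(rs)
      st0 <- rep(records$start[idx], each = k)
      S[[u]] <- st0 + rep(rs, n)
      E[[u]] <- st0 + rep(re, n)
      wfix <- ifelse(ty == "=", 1, ifelse(ty %in% c("X", "D"), -1, NA))
      wm <- rep(ifelse(m_ok[idx], 1, -1), each = k)
      W[[u]] <- ifelse(is.na(rep(wfix, n)), wm, rep(wfix, n))
    }
    if (length(ip)) {
      P[[u]] <- pmax(1L, rep(records$start[idx], each = length(ip)) +
                       rep(ip, length(idx)))
    }
  }
  acc <- interval_accumulate(L, unlist(S, use.names = FALSE),
                             unlist(E, use.names = FALSE),
                             unlist(W, use.names = FALSE))
  pts <- unlist(P, use.names = FALSE)
  if (length(pts)) acc <- acc + point_accumulate(L, pts, rep(-1, length(pts)))
  as.integer(sign(acc))
}

#' Per-read coverage deviation flags of one contig
#'
#' Computes per-base read depth from the reference spans, the mean depth
#' rc_i over each read's span, and flags reads whose rc_i deviates from the
#' contig mean by more than `sigma_mult` standard deviations (+1) or not (-1).
#'
#' @param contig_id contig.
#' @param contig_length its length.
#' @param records alignment records on that contig.
#' @param sigma_mult deviation threshold in standard deviations (default 2).
#' @return list with `rc_bar`, `sigma_rc`, `rc_i`, and `flags` (one per read).
#' @export
coverage_flags <- function(contig_id, contig_length, records, sigma_mult = 2) {
  records <- records[records$contig_id == contig_id, , drop = FALSE]
  if (!nrow(records)) {
    return(list(rc_bar = NA_real_, sigma_rc = NA_real_, rc_i = numeric(0),
                flags = integer(0)))
  }
  depth <- interval_accumulate(contig_length, records$start,
                               records$start + records$ref_span)
  cum <- c(0, cumsum(depth))
  s <- records$start; e <- records$start + records$ref_span
  rc_i <- (cum[e + 1L] - cum[s + 1L]) / (e - s)
  rc_bar <- mean(rc_i)
  sigma_rc <- if (length(rc_i) > 1L) stats::sd(rc_i) else 0
  flags <- ifelse(rc_i > rc_bar + sigma_mult * sigma_rc |
                    rc_i < rc_bar - sigma_mult * sigma_rc, 1L, -1L)
  list(rc_bar = rc_bar, sigma_rc = sigma_rc, rc_i = rc_i, flags = flags)
}

#' Overall score of one assembly
#'
#' score = (sum over contigs of sum_j q_j - sum over contigs of sum_i RC_i) / N
#' where N is the number of contigs in the set.
#'
#' @param set a `contig_set`.
#' @param records preprocessed alignment records against this set.
#' @return list with `set_id`, `score`, `sum_q`, `sum_rc`, `n_contigs`.
#' @export
assembly_score <- function(set, records) {
  lens <- contig_lengths(set)
  if (!nrow(records)) {
    warning("no aligned reads for set ", set$set_id, "; coverage term is 0")
  }
  mm <- if (nrow(records)) mean_mapping_score(records) else 0
  sum_q <- 0; sum_rc <- 0
  for (cid in names(lens)) {
    on_c <- records[records$contig_id == cid, , drop = FALSE]
    if (!nrow(on_c)) next
    sum_q <- sum_q + sum(position_quality_profile(cid, lens[[cid]], on_c, mm))
    sum_rc <- sum_rc + sum(coverage_flags(cid, lens[[cid]], on_c)$flags)
  }
  n <- length(lens)
  list(set_id = set$set_id, score = (sum_q - sum_rc) / n,
       sum_q = sum_q, sum_rc = sum_rc, n_contigs = n)
}

#' Rank assemblies by score
#'
#' @param scores list of score objects from [assembly_score()].
#' @return character vector of set_ids, best first; ties keep input order.
#' @export
rank_assemblies <- function(scores) {
  if (length(scores) < 2L) stop("ranking needs at least two assemblies")
  s <- vapply(scores, `[[`, numeric(1), "score")
  ids <- vapply(scores, `[[`, character(1), "set_id")
  ids[order(-s)]  # order() is stable, ties keep input order
}

#' Per-assembly ranking report
#' @param scores list of score objects.
#' @return data.frame with one row per assembly, ranked.
#' @export
ranking_report <- function(scores) {
  df <- do.call(rbind, lapply(scores, function(x) {
    data.frame(set_id = x$set_id, sum_q = x$sum_q, sum_rc = x$sum_rc,
               n_contigs = x$n_contigs, score = x$score,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$score), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
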