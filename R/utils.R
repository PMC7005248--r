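# Internal helpers shared across modules. All interval coordinates are
# 0-based half-open; per-position profiles are R vectors indexed 1..L, so
# a span [s, e) covers vector positions (s+1)..e.

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string, e.g. "3M2I4M".
#' @return data.frame with columns `op` and `len`.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(data.frame(op = character(0), len = integer(0)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || any(is.na(lens))) {
    stop("malformed CIGAR string: ", cigar)
  }
  bad <- setdiff(ops, c("M", "I", "D", "S", "H", "=", "X"))
  if (length(bad)) stop("unsupported CIGAR operator(s) ", paste(bad, collapse = ","),
                        " in ", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# per-CIGAR summary, memoised over unique strings for vector input
cigar_spans <- function(cigars) {
  uq <- unique(cigars)
  ref <- integer(length(uq))
  qry <- integer(length(uq))
  for (i in seq_along(uq)) {
    cp <- parse_cigar(uq[i])
    ref[i] <- sum(cp$len[cp$op %in% c("M", "D", "=", "X")])
    qry[i] <- sum(cp$len[cp$op %in% c("M", "I", "S", "=", "X")])
  }
  idx <- match(cigars, uq)
  list(ref_span = ref[idx], query_len = qry[idx])
}

#' Reverse complement of a nucleotide string
#' @param x character vector of sequences over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# weighted interval accumulation: adds w[i] over vector positions
# (starts0[i]+1)..ends0[i] of a length-L profile (0-based half-open spans).
interval_accumulate <- function(L, starts0, ends0, w = rep(1, length(starts0))) {
  stopifnot(length(starts0) == length(ends0))
  acc <- numeric(L + 1L)
  keep <- ends0 > starts0
  starts0 <- pmax(0L, starts0[keep]); ends0 <- pmin(L, ends0[keep]); w <- w[keep]
  if (length(starts0)) {
    up <- rowsum(w, starts0 + 1L)
    acc[as.integer(rownames(up))] <- acc[as.integer(rownames(up))] + up[, 1L]
    dn <- rowsum(w, ends0 + 1L)
    acc[as.integer(rownames(dn))] <- acc[as.integer(rownames(dn))] - dn[, 1L]
  }
  cumsum(acc)[seq_len(L)]
}

# point accumulation at 1-based positions
point_accumulate <- function(L, pos1, w = rep(1, length(pos1))) {
  acc <- numeric(L)
  keep <- pos1 >= 1L & pos1 <= L
  pos1 <- pos1[keep]; w <- w[keep]
  if (length(pos1)) {
    up <- rowsum(w, pos1)
    acc[as.integer(rownames(up))] <- up[, 1L]
  }
  acc
}

#' N50 of a set of sequence lengths
#'
#' Length such that sequences at least that long cover half the total.
#'
#' @param lengths integer vector of sequence lengths.
#' @return the N50 value.
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (!length(lengths)) return(0)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]]
}

# GC percent of a sequence (N counts in the denominator only)
gc_percent <- function(seq) {
  n <- nchar(seq)
  if (sum(n) == 0) return(NA_real_)
  gc <- vapply(gregexpr("[GC]", seq), function(m) sum(m > 0L), integer(1))
  100 * sum(gc) / sum(n)
}
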