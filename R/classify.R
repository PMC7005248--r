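# Contig classification. Low fragment-coverage regions are candidate
# misassembly sites; mate-pair support and GC content of the flanking
# sequence decide whether a candidate is certainly false (the contig is
# broken there) or merely uncertain (the breakpoint is recorded and the
# contig labeled U). Contigs without surviving candidates are labeled T.

#' Per-position fragment coverage of one contig
#'
#' fc(j) = number of retained reads whose reference span covers position j.
#' By default only clip-free alignments count: a soft-clipped read does not
#' truly span the positions it touches — the read disagrees with the contig
#' beyond the clip point, which is exactly the signal at a misjoin.
#'
#' @param contig_id contig.
#' @param contig_length its length.
#' @param records preprocessed alignment records.
#' @param full_length_only count only alignments without soft clips
#'   (default TRUE).
#' @return integer vector fc of length `contig_length`.
#' @export
fragment_coverage_profile <- function(contig_id, contig_length, records,
                                      full_length_only = TRUE) {
  records <- records[records$contig_id == contig_id, , drop = FALSE]
  if (full_length_only && nrow(records)) {
    records <- records[!grepl("S", records$cigar, fixed = TRUE), , drop = FALSE]
  }
  if (!nrow(records)) return(integer(contig_length))
  as.integer(interval_accumulate(contig_length, records$start,
                                 records$start + records$ref_span))
}

#' Coverage cutoff for candidate-region detection
#'
#' fc* = alpha times the mean fragment coverage of the contig.
#'
#' @param fc fragment coverage profile.
#' @param alpha scaling factor (default 0.5).
#' @return the cutoff fc*.
#' @export
coverage_cutoff <- function(fc, alpha = 0.5) {
  stopifnot(length(fc) >= 1L, alpha > 0)
  alpha * mean(fc)
}

#' Detect candidate misassembly regions
#'
#' Maximal runs of positions with fc(j) <= fc* become regions [m, n]
#' (1-based, inclusive); the breakpoint b_p is the leftmost position of
#' minimal coverage within the region. Positions within `edge_trim` of either
#' contig end are excluded: coverage necessarily ramps down at contig
#' termini, which is geometry rather than evidence.
#'
#' @param fc fragment coverage profile.
#' @param fc_star cutoff from [coverage_cutoff()].
#' @param edge_trim positions to ignore at each contig end (default 0;
#'   pipeline callers pass the read length).
#' @return data.frame with columns m, n, b_p, fc_bp (possibly 0 rows).
#' @export
detect_candidate_regions <- function(fc, fc_star, edge_trim = 0L) {
  L <- length(fc)
  low <- fc <= fc_star
  if (edge_trim > 0L) {
    lo <- min(edge_trim, L); hi <- max(1L, L - edge_trim + 1L)
    low[seq_len(lo)] <- FALSE
    low[hi:L] <- FALSE
  }
  if (!any(low)) {
    return(data.frame(m = integer(0), n = integer(0), b_p = integer(0),
                      fc_bp = integer(0)))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- starts[r$values]; n <- ends[r$values]
  b_p <- integer(length(m)); fc_bp <- integer(length(m))
  for (i in seq_along(m)) {
    seg <- fc[m[i]:n[i]]
    k <- which.min(seg)  # leftmost minimum
    b_p[i] <- m[i] + k - 1L
    fc_bp[i] <- seg[k]
  }
  data.frame(m = m, n = n, b_p = b_p, fc_bp = fc_bp)
}

#' Mate support rates at a breakpoint
#'
#' M_s counts read alignments whose leftmost position lies in the left flank
#' [b_p - flank, b_p) of the breakpoint and whose mate maps to a different
#' contig; M_p is symmetric on the right flank. The rates are
#' P_cs = fc(b_p) / (fc(b_p) + M_s) and P_cp = fc(b_p) / (fc(b_p) + M_p);
#' a 0/0 case is defined as 1.
#'
#' @param b_p breakpoint position (1-based).
#' @param fc_bp fragment coverage at the breakpoint.
#' @param contig_id contig.
#' @param records preprocessed alignment records (all contigs: mates needed).
#' @param flank flank width in bases.
#' @return list with M_s, M_p, P_cs, P_cp.
#' @export
mate_support_rates <- function(b_p, fc_bp, contig_id, records, flank) {
  on_c <- records[records$contig_id == contig_id &
                    !is.na(records$mate_contig_id) &
                    records$mate_contig_id != contig_id, , drop = FALSE]
  p1 <- on_c$start + 1L
  p2 <- on_c$start + on_c$ref_span
  m_s <- sum(p1 >= b_p - flank & p1 < b_p)
  m_p <- sum(p2 > b_p & p2 <= b_p + flank)
  rate <- function(m) if (fc_bp == 0 && m == 0) 1 else fc_bp / (fc_bp + m)
  list(M_s = m_s, M_p = m_p, P_cs = rate(m_s), P_cp = rate(m_p))
}

#' GC content of a whole contig set, in percent
#'
#' Fraction of G/C bases over all contigs; N bases count in the denominator
#' only.
#'
#' @param set a `contig_set`.
#' @return GC percentage P_g.
#' @export
genome_gc_content <- function(set) {
  gc_percent(set$contigs)
}

#' GC label of a candidate region
#'
#' P_GC is the GC percentage of the region extended by `flank` on both sides
#' (clamped to the contig). The region is `rich` iff P_GC >= P_g + 1
#' percentage point, `poor` iff P_GC <= P_g - 1, otherwise `neutral`.
#'
#' @param m,n region bounds (1-based inclusive).
#' @param sequence the contig sequence.
#' @param p_g whole-set GC percentage.
#' @param flank extension width in bases (default 0).
#' @return one of "rich", "poor", "neutral", plus the P_GC value, as a list.
#' @export
region_gc_label <- function(m, n, sequence, p_g, flank = 0L) {
  L <- nchar(sequence)
  a <- max(1L, m - flank); b <- min(L, n + flank)
  p_gc <- gc_percent(substr(sequence, a, b))
  label <- if (p_gc >= p_g + 1) "rich" else if (p_gc <= p_g - 1) "poor" else "neutral"
  list(label = label, p_gc = p_gc)
}

#' Classify contigs and break them at certainly-false positions
#'
#' For each contig, candidate regions are detected from fragment coverage and
#' given a verdict: `certainly_false` when mate support is weak on both sides
#' (P_cs <= beta and P_cp <= beta) and the local GC content is neutral;
#' `uncertain` otherwise (the region is rescued by mate support or GC bias).
#' Contigs are split at every certainly-false breakpoint (fragments named
#' `<id>.1`, `<id>.2`, ...; fragments shorter than `min_fragment` are dropped
#' and logged). Surviving fragments are labeled U iff they still contain an
#' uncertain breakpoint (remapped into fragment coordinates), else T.
#'
#' @param set a `contig_set`.
#' @param records preprocessed alignment records against this set.
#' @param alpha coverage cutoff factor (default 0.5).
#' @param beta mate-support rate threshold (default 0.8).
#' @param flank flank width in bases (typically the insert-size mean).
#' @param min_fragment minimum emitted fragment length (default 200).
#' @param edge_trim contig-end positions excluded from candidate detection
#'   (default 100; pass the read length).
#' @return list with `set` (the possibly split `contig_set`), `classification`
#'   (named list per fragment: label, error_positions), `regions` (the
#'   per-region report data.frame), and `dropped` (sub-minimum fragments).
#' @export
classify_and_break <- function(set, records, alpha = 0.5, beta = 0.8,
                               flank = 300L, min_fragment = 200L,
                               edge_trim = 100L) {
  p_g <- genome_gc_content(set)
  lens <- contig_lengths(set)
  new_seqs <- character(0)
  classification <- list()
  dropped <- character(0)
  region_rows <- list()
  for (cid in names(lens)) {
    L <- lens[[cid]]
    seqc <- set$contigs[[cid]]
    fc <- fragment_coverage_profile(cid, L, records)
    regions <- if (any(fc > 0)) {
      detect_candidate_regions(fc, coverage_cutoff(fc, alpha), edge_trim)
    } else {
      data.frame(m = integer(0), n = integer(0), b_p = integer(0),
                 fc_bp = integer(0))
    }
    false_bp <- integer(0); uncertain_bp <- integer(0)
    if (nrow(regions)) {
      for (i in seq_len(nrow(regions))) {
        ms <- mate_support_rates(regions$b_p[i], regions$fc_bp[i], cid,
                                 records, flank)
        gc <- region_gc_label(regions$m[i], regions$n[i], seqc, p_g, flank)
        certainly_false <- ms$P_cs <= beta && ms$P_cp <= beta &&
          gc$label == "neutral"
        if (certainly_false) {
          false_bp <- c(false_bp, regions$b_p[i])
        } else {
          uncertain_bp <- c(uncertain_bp, regions$b_p[i])
        }
        region_rows[[length(region_rows) + 1L]] <- data.frame(
          contig_id = cid, m = regions$m[i], n = regions$n[i],
          b_p = regions$b_p[i], fc_bp = regions$fc_bp[i],
          P_cs = ms$P_cs, P_cp = ms$P_cp, P_GC = gc$p_gc,
          verdict = if (certainly_false) "certainly_false" else "uncertain",
          stringsAsFactors = FALSE)
      }
    }
    # split at certainly-false breakpoints: left fragment keeps 1..b_p
    cuts <- sort(unique(false_bp))
    bounds <- c(0L, cuts, L)
    n_frag <- length(bounds) - 1L
    for (k in seq_len(n_frag)) {
      a <- bounds[k] + 1L; b <- bounds[k + 1L]
      if (b < a) next
      frag_id <- if (n_frag == 1L) cid else paste0(cid, ".", k)
      frag_len <- b - a + 1L
      if (frag_len < min_fragment && n_frag > 1L) {
        dropped <- c(dropped, frag_id)
        next
      }
      new_seqs[[frag_id]] <- substr(seqc, a, b)
      ub <- uncertain_bp[uncertain_bp >= a & uncertain_bp <= b] - (a - 1L)
      classification[[frag_id]] <- list(
        contig_id = frag_id,
        label = if (length(ub)) "U" else "T",
        error_positions = as.integer(ub),
        source_contig = cid, source_offset = a - 1L)
    }
  }
  regions_df <- if (length(region_rows)) do.call(rbind, region_rows) else
    data.frame(contig_id = character(0), m = integer(0), n = integer(0),
               b_p = integer(0), fc_bp = integer(0), P_cs = numeric(0),
               P_cp = numeric(0), P_GC = numeric(0), verdict = character(0),
               stringsAsFactors = FALSE)
  list(set = contig_set(new_seqs, set_id = set$set_id),
       classification = classification, regions = regions_df,
       dropped = dropped)
}

#' Per-contig classification report
#' @param result output of [classify_and_break()].
#' @return data.frame: one row per surviving fragment.
#' @export
classification_report <- function(result) {
  do.call(rbind, lapply(result$classification, function(cl) {
    data.frame(contig_id = cl$contig_id, label = cl$label,
               error_positions = paste(cl$error_positions, collapse = ","),
               source_contig = cl$source_contig,
               stringsAsFactors = FALSE)
  }))
}
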