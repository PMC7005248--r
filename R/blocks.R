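# Consensus blocks and adjacency chains. Block matches between the two
# contig sets are filtered, de-overlapped (longest wins) and numbered; each
# contig is then encoded as an ordered chain of signed block ids. Canonical
# block orientation is the orientation in set O (the higher-ranked input),
# so O-chains carry positive signs and R-chains are signed by match strand.

#' Identify consensus blocks from raw block matches
#'
#' Matches are filtered by minimum length and identity; overlapping matches
#' on the same contig (in either set) are resolved by keeping the longest.
#' Survivors are numbered 1..B in order of (O-contig input order, o_start).
#'
#' @param matches block matches (see [parse_coords_table()]).
#' @param o_set,r_set the two contig sets (O is the higher ranked); used for
#'   contig input order and bounds checking.
#' @param min_len minimum block length in bases (default 200).
#' @param min_identity minimum match identity (default 0.95).
#' @return data.frame of blocks: block_id, o_contig, o_start, o_end,
#'   r_contig, r_start, r_end, same_strand, length.
#' @export
find_consensus_blocks <- function(matches, o_set, r_set, min_len = 200L,
                                  min_identity = 0.95) {
  if (!nrow(matches)) return(cbind(block_id = integer(0), empty_block_matches(),
                                   length = numeric(0)))
  len <- pmin(matches$o_end - matches$o_start, matches$r_end - matches$r_start)
  keep <- len >= min_len & matches$identity >= min_identity
  matches <- matches[keep, , drop = FALSE]
  len <- len[keep]
  if (!nrow(matches)) return(cbind(block_id = integer(0), empty_block_matches(),
                                   length = numeric(0)))
  # greedy conflict resolution, longest first: a new block overlapping an
  # already-kept block is trimmed back to the free interval (overlaps arise
  # from chance extension of exact matches past true boundaries, and from
  # repeat copies); blocks trimmed below min_len are dropped
  ord <- order(-len, matches$o_contig, matches$o_start)
  kept <- list()
  for (i in ord) {
    cand <- matches[i, , drop = FALSE]
    ok <- TRUE
    for (pass in 1:4) {  # trims on one side can expose overlap on the other
      changed <- FALSE
      for (j in seq_along(kept)) {
        cand2 <- trim_match(cand, kept[[j]])
        if (is.null(cand2)) { ok <- FALSE; break }
        if (!identical(cand2, cand)) { cand <- cand2; changed <- TRUE }
      }
      if (!ok || !changed) break
    }
    if (ok && min(cand$o_end - cand$o_start,
                  cand$r_end - cand$r_start) >= min_len) {
      kept[[length(kept) + 1L]] <- cand
    }
  }
  if (!length(kept)) return(cbind(block_id = integer(0), empty_block_matches(),
                                  length = numeric(0)))
  blocks <- do.call(rbind, kept)
  o_order <- match(blocks$o_contig, names(o_set$contigs))
  blocks <- blocks[order(o_order, blocks$o_start), , drop = FALSE]
  blocks$length <- pmin(blocks$o_end - blocks$o_start,
                        blocks$r_end - blocks$r_start)
  blocks <- cbind(block_id = seq_len(nrow(blocks)), blocks)
  rownames(blocks) <- NULL
  blocks
}

# trim candidate match `m` so it no longer overlaps kept match `k` on either
# contig; the paired coordinates stay colinear (a left trim on one set trims
# the strand-matching side of the other). Returns NULL when nothing is left.
trim_match <- function(m, k) {
  trim <- function(m, side, amount) {
    if (amount <= 0) return(m)
    if (side == "o_left") {
      m$o_start <- m$o_start + amount
      if (m$same_strand) m$r_start <- m$r_start + amount
      else m$r_end <- m$r_end - amount
    } else if (side == "o_right") {
      m$o_end <- m$o_end - amount
      if (m$same_strand) m$r_end <- m$r_end - amount
      else m$r_start <- m$r_start + amount
    } else if (side == "r_left") {
      m$r_start <- m$r_start + amount
      if (m$same_strand) m$o_start <- m$o_start + amount
      else m$o_end <- m$o_end - amount
    } else {
      m$r_end <- m$r_end - amount
      if (m$same_strand) m$o_end <- m$o_end - amount
      else m$o_start <- m$o_start + amount
    }
    m
  }
  for (set in c("o", "r")) {
    sc <- paste0(set, "_contig"); ss <- paste0(set, "_start"); se <- paste0(set, "_end")
    if (m[[sc]] != k[[sc]]) next
    if (m[[ss]] >= k[[se]] || m[[se]] <= k[[ss]]) next
    if (m[[ss]] >= k[[ss]] && m[[se]] <= k[[se]]) return(NULL)  # contained
    if (m[[ss]] < k[[ss]] && m[[se]] > k[[se]]) {
      # candidate strictly contains the kept block: keep the longer free side
      left <- k[[ss]] - m[[ss]]; right <- m[[se]] - k[[se]]
      if (left >= right) m <- trim(m, paste0(set, "_right"), m[[se]] - k[[ss]])
      else m <- trim(m, paste0(set, "_left"), k[[se]] - m[[ss]])
    } else if (m[[ss]] < k[[ss]]) {
      m <- trim(m, paste0(set, "_right"), m[[se]] - k[[ss]])
    } else {
      m <- trim(m, paste0(set, "_left"), k[[se]] - m[[ss]])
    }
    if (m$o_end <= m$o_start || m$r_end <= m$r_start) return(NULL)
  }
  m
}

# chain constructor: blocks is a signed integer vector; errs holds adjacency
# indices i meaning "a retained error position sits between blocks[i] and
# blocks[i+1]"; starts/ends give each block's placement on the source contig
# (NA once chains have been fused across contigs).
new_chain <- function(id, set_tag, blocks, starts = rep(NA_real_, length(blocks)),
                      ends = rep(NA_real_, length(blocks)), errs = integer(0)) {
  structure(list(id = id, set_tag = set_tag, blocks = as.integer(blocks),
                 starts = starts, ends = ends, errs = as.integer(errs)),
            class = "adjacency_chain")
}

#' @export
print.adjacency_chain <- function(x, ...) {
  cat(sprintf("%s %s [%s]%s\n", x$set_tag, x$id,
              paste(x$blocks, collapse = ","),
              if (length(x$errs)) paste0(" errs@", paste(x$errs, collapse = ","))
              else ""))
  invisible(x)
}

# reverse a chain, flipping block signs (orientation reversal)
revneg_chain <- function(ch) {
  k <- length(ch$blocks)
  new_chain(ch$id, ch$set_tag, rev(-ch$blocks), rev(ch$starts), rev(ch$ends),
            if (length(ch$errs)) sort(k - ch$errs) else integer(0))
}

# canonical orientation: the smallest absolute block id appears with
# positive sign if possible; ties broken lexicographically
canonicalize_chain <- function(ch) {
  rv <- revneg_chain(ch)
  m <- min(abs(ch$blocks))
  s_f <- ch$blocks[abs(ch$blocks) == m][1L]
  s_r <- rv$blocks[abs(rv$blocks) == m][1L]
  if (s_f > 0 && s_r < 0) return(ch)
  if (s_r > 0 && s_f < 0) return(rv)
  if (paste(ch$blocks, collapse = ",") <= paste(rv$blocks, collapse = ",")) ch else rv
}

#' Test whether two signed block chains are equivalent
#'
#' Equal either directly or after reversing one chain and flipping signs.
#'
#' @param a,b signed integer vectors.
#' @return TRUE or FALSE.
#' @export
chain_equivalent <- function(a, b) {
  identical(as.integer(a), as.integer(b)) ||
    identical(as.integer(a), rev(-as.integer(b)))
}

#' Build adjacency chains for one contig set
#'
#' Per contig, blocks are sorted by start; consecutive blocks are adjacent
#' iff their gap is at most `g_max` bases, or they overlap end-to-end by at
#' most 1% of the shorter block. Non-adjacent consecutive blocks split the
#' chain. Reversed placements (R set, opposite strand) get negative signs.
#'
#' @param set a `contig_set`.
#' @param blocks consensus block table from [find_consensus_blocks()].
#' @param set_tag "O" or "R": which placement columns to read.
#' @param g_max maximum gap for adjacency (default 10).
#' @return list of `adjacency_chain` objects.
#' @export
build_adjacency_chains <- function(set, blocks, set_tag = c("O", "R"),
                                   g_max = 10L) {
  set_tag <- match.arg(set_tag)
  pfx <- if (set_tag == "O") "o" else "r"
  ctg <- blocks[[paste0(pfx, "_contig")]]
  bst <- blocks[[paste0(pfx, "_start")]]
  ben <- blocks[[paste0(pfx, "_end")]]
  lens <- contig_lengths(set)
  if (nrow(blocks)) {
    unknown <- setdiff(ctg, names(lens))
    if (length(unknown)) stop("block placed on unknown contig ", unknown[1L])
    if (any(bst < 0 | ben > lens[ctg])) {
      stop("block placement outside contig bounds in set ", set_tag)
    }
  }
  chains <- list()
  for (cid in names(lens)) {
    idx <- which(ctg == cid)
    if (!length(idx)) next
    idx <- idx[order(bst[idx])]
    sign_v <- if (set_tag == "O") rep(1L, length(idx)) else
      ifelse(blocks$same_strand[idx], 1L, -1L)
    signed <- sign_v * blocks$block_id[idx]
    # break the chain where consecutive blocks are not adjacent
    part <- 1L
    grp <- integer(length(idx)); grp[1L] <- part
    for (k in seq_along(idx)[-1L]) {
      gap <- bst[idx[k]] - ben[idx[k - 1L]]
      lmin <- min(blocks$length[idx[k]], blocks$length[idx[k - 1L]])
      adjacent <- (gap >= 0 && gap <= g_max) || (gap < 0 && -gap <= 0.01 * lmin)
      if (!adjacent) part <- part + 1L
      grp[k] <- part
    }
    for (p in unique(grp)) {
      sel <- grp == p
      chains[[length(chains) + 1L]] <- new_chain(
        id = if (max(grp) == 1L) cid else paste0(cid, "/", p),
        set_tag = set_tag, blocks = signed[sel],
        starts = bst[idx[sel]], ends = ben[idx[sel]])
    }
  }
  chains
}

#' Carry classified error positions onto a chain
#'
#' Uncertain positions of the chain's contig are kept iff they fall in an
#' adjacent region: the gap/overlap zone between two consecutive blocks,
#' extended by `flank` into each block. Positions deep inside a block are
#' discarded. T contigs pass through unchanged.
#'
#' @param chain an `adjacency_chain` (placements still on one contig).
#' @param classification per-contig classification entry (label,
#'   error_positions) or NULL.
#' @param flank zone extension in bases (default 100).
#' @return the chain with its `errs` field populated.
#' @export
carry_error_positions <- function(chain, classification, flank = 100L) {
  if (is.null(classification) || classification$label != "U" ||
      !length(classification$error_positions) || length(chain$blocks) < 2L) {
    return(chain)
  }
  errs <- integer(0)
  for (i in seq_len(length(chain$blocks) - 1L)) {
    lo <- chain$ends[i] - flank       # 0-based
    hi <- chain$starts[i + 1L] + flank
    pos <- classification$error_positions
    if (any(pos > lo & pos <= hi)) errs <- c(errs, i)
  }
  chain$errs <- errs
  chain
}

#' Text dump of adjacency chains
#' @param chains list of chains.
#' @return character vector, one line per chain, e.g. `O c1 [1,5]`.
#' @export
dump_chains <- function(chains) {
  vapply(chains, function(ch) {
    sprintf("%s %s [%s]", ch$set_tag, ch$id, paste(ch$blocks, collapse = ","))
  }, character(1))
}
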