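# Synthetic data: genomes with controllable GC and planted repeats,
# fragmented assemblies with planted misjoins and exhaustive truth tables,
# paired reads with quality strings, truth-driven alignments, an exact
# k-mer block matcher for tests, and the canonical nine-block worked
# example. Every generator is a pure function of its seed and plan.

#' Simulate a genome sequence
#'
#' Bases are drawn i.i.d. with P(G)=P(C)=gc/2; planted repeats are
#' byte-identical copies pasted over the background at the given placements.
#'
#' @param length genome length in bases.
#' @param gc target GC fraction (default 0.5).
#' @param repeats optional data.frame with columns `length` and `at` (a list
#'   column or comma string of 0-based placements); all copies of one row are
#'   identical.
#' @param repeat_gc GC fraction of the repeat sequence (defaults to `gc`).
#' @param seed RNG seed.
#' @return a single uppercase sequence string.
#' @export
simulate_genome <- function(length, gc = 0.5, repeats = NULL,
                            repeat_gc = gc, seed = 1L) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  rng <- local_rng(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- sample(names(p), length, replace = TRUE, prob = p)
  if (!is.null(repeats) && nrow(repeats)) {
    placements <- list()
    for (i in seq_len(nrow(repeats))) {
      at <- repeats$at[[i]]
      if (is.character(at)) at <- as.integer(strsplit(at, ",")[[1]])
      rl <- repeats$length[i]
      if (any(at < 0 | at + rl > length)) stop("repeat placement outside genome")
      pr <- c(A = (1 - repeat_gc) / 2, C = repeat_gc / 2,
              G = repeat_gc / 2, T = (1 - repeat_gc) / 2)
      rep_seq <- sample(names(pr), rl, replace = TRUE, prob = pr)
      for (a in at) {
        iv <- (a + 1L):(a + rl)
        for (pl in placements) {
          if (min(iv) <= max(pl) && max(iv) >= min(pl)) {
            stop("overlapping repeat placements")
          }
        }
        placements[[length(placements) + 1L]] <- range(iv)
        g[iv] <- rep_seq
      }
    }
  }
  paste(g, collapse = "")
}

# seed the RNG for a generator body, restoring the caller-visible state on
# exit so generators do not perturb the global random stream
local_rng <- function(seed, env = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  restore <- if (has_old) {
    substitute(assign(".Random.seed", OLD, envir = globalenv()),
               list(OLD = get(".Random.seed", envir = globalenv())))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

#' Simulate assemblies from a genome
#'
#' Each assembly is described by a contig plan: a list of contigs, each a
#' data.frame of genome segments (`start`, `end`, 0-based half-open) that are
#' concatenated in order. A contig with more than one non-contiguous segment
#' is a planted misjoin. The helper [assembly_plan_from_breaks()] builds the
#' common case of clean cuts.
#'
#' @param genome genome sequence string.
#' @param plans named list (one per assembly) of contig plans.
#' @return list with `sets` (list of `contig_set`) and `truth` (data.frame:
#'   set_id, contig_id, contig_start, contig_end, genome_start, genome_end —
#'   every emitted base covered exactly once).
#' @export
simulate_assemblies <- function(genome, plans) {
  G <- nchar(genome)
  sets <- list()
  truth <- list()
  for (aid in names(plans)) {
    plan <- plans[[aid]]
    seqs <- character(0)
    for (ci in seq_along(plan)) {
      segs <- plan[[ci]]
      if (any(segs$start < 0 | segs$end > G | segs$end <= segs$start)) {
        stop("segment outside genome in assembly ", aid)
      }
      cid <- sprintf("%s_c%d", aid, ci)
      parts <- substring(genome, segs$start + 1L, segs$end)
      seqs[[cid]] <- paste(parts, collapse = "")
      off <- c(0L, cumsum(segs$end - segs$start))
      truth[[length(truth) + 1L]] <- data.frame(
        set_id = aid, contig_id = cid,
        contig_start = off[-length(off)], contig_end = off[-1L],
        genome_start = segs$start, genome_end = segs$end,
        stringsAsFactors = FALSE)
    }
    sets[[aid]] <- contig_set(seqs, set_id = aid)
  }
  list(sets = sets, truth = do.call(rbind, truth))
}

#' Contig plan from clean breakpoints
#'
#' @param genome_length genome length.
#' @param breaks sorted 0-based cut positions (strictly inside the genome).
#' @return a contig plan: consecutive genome segments, no misjoins.
#' @export
assembly_plan_from_breaks <- function(genome_length, breaks) {
  breaks <- sort(unique(as.integer(breaks)))
  stopifnot(all(breaks > 0 & breaks < genome_length))
  bounds <- c(0L, breaks, genome_length)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    data.frame(start = bounds[i], end = bounds[i + 1L])
  })
}

#' Simulate paired-end reads
#'
#' Fragment starts are uniform (or an exact even tiling when
#' `spacing = "uniform"`); insert lengths are normal(mu, sigma) truncated to
#' [read_len, genome length]. Read 1 is the forward strand of the fragment's
#' left end, read 2 the reverse complement of its right end. Substitution
#' errors occur at `error_rate`, preferentially at low-quality bases; the
#' quality model is two-state (high Q38, low Q12) with a low-quality tail.
#'
#' @param genome genome sequence string.
#' @param n_pairs number of read pairs.
#' @param read_len read length.
#' @param insert_mu,insert_sigma insert-size model.
#' @param error_rate substitution rate (default 0).
#' @param low_q_tail fraction of each read's 3' end at low quality
#'   (default 0.1).
#' @param spacing "random" fragment starts, or "uniform" even tiling.
#' @param seed RNG seed.
#' @return list with `reads` (data.frame: read_id, mate, seq, qual,
#'   genome_start, genome_end, strand — the truth of each read) and the model
#'   parameters.
#' @export
simulate_reads <- function(genome, n_pairs, read_len = 100L, insert_mu = 300,
                           insert_sigma = 30, error_rate = 0,
                           low_q_tail = 0.1, spacing = c("random", "uniform"),
                           seed = 1L) {
  spacing <- match.arg(spacing)
  G <- nchar(genome)
  if (insert_mu <= read_len) stop("insert_mu must exceed read_len")
  if (G < insert_mu + 4 * insert_sigma) stop("genome too short for this insert size")
  rng <- local_rng(seed)
  ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mu, insert_sigma)),
                   read_len), G)
  starts <- if (spacing == "uniform") {
    floor(seq(0, G - max(ins), length.out = n_pairs))
  } else {
    floor(stats::runif(n_pairs, 0, G - ins + 1))
  }
  starts <- pmin(pmax(starts, 0), G - ins)
  r1_s <- starts
  r2_s <- starts + ins - read_len
  seq1 <- substring(genome, r1_s + 1L, r1_s + read_len)
  seq2 <- revcomp(substring(genome, r2_s + 1L, r2_s + read_len))
  qual <- quality_strings(n_pairs * 2L, read_len, low_q_tail)
  if (error_rate > 0) {
    seq1 <- apply_errors(seq1, qual[seq_len(n_pairs)], error_rate)
    seq2 <- apply_errors(seq2, qual[n_pairs + seq_len(n_pairs)], error_rate)
  }
  ids <- sprintf("rp%06d", seq_len(n_pairs))
  reads <- rbind(
    data.frame(read_id = ids, mate = 1L, seq = seq1,
               qual = qual[seq_len(n_pairs)],
               genome_start = r1_s, genome_end = r1_s + read_len,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(read_id = ids, mate = 2L, seq = seq2,
               qual = qual[n_pairs + seq_len(n_pairs)],
               genome_start = r2_s, genome_end = r2_s + read_len,
               strand = "-", stringsAsFactors = FALSE))
  list(reads = reads, read_len = read_len, insert_mu = insert_mu,
       insert_sigma = insert_sigma, inserts = ins)
}

# two-state quality strings: Q38 head, Q12 tail over the last `tail_frac`
quality_strings <- function(n, read_len, tail_frac) {
  n_low <- round(read_len * tail_frac)
  q <- c(rep(38L, read_len - n_low), rep(12L, n_low))
  rep(rawToChar(as.raw(q + 33L)), n)
}

# substitution errors, biased toward low-quality bases
apply_errors <- function(seqs, quals, rate) {
  q <- as.integer(charToRaw(quals[1L])) - 33L  # one shared quality model
  w <- 10^(-q / 10)
  w <- w / mean(w)
  rl <- nchar(seqs[1L])
  n_err <- stats::rpois(length(seqs), rate * rl)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(rl, min(n_err[i], rl), prob = w)
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Write simulated reads to paired FASTQ files
#' @param sim output of [simulate_reads()].
#' @param prefix path prefix; writes `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#' @return invisibly, the two paths.
#' @export
write_fastq_pair <- function(sim, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    r <- sim$reads[sim$reads$mate == m, , drop = FALSE]
    writeLines(paste0("@", r$read_id, "/", m, "\n", r$seq, "\n+\n", r$qual),
               paths[m])
  }
  invisible(paths)
}

#' Place simulated reads on an assembly from truth
#'
#' Maps each read to the assembly contig holding its true genome interval,
#' using the assembly truth table; no aligner is involved. A read whose
#' interval crosses a contig-segment boundary is soft-clipped to the segment
#' holding the larger part (dropped as unmapped when the anchor is shorter
#' than `min_anchor`). All alignments get MAPQ `mapq`.
#'
#' @param sim output of [simulate_reads()].
#' @param truth assembly truth table of ONE set (rows of
#'   [simulate_assemblies()] `truth` with one set_id).
#' @param mapq mapping quality assigned (default 60).
#' @param min_anchor minimum mapped bases (default 20).
#' @return alignment records in the format of [parse_sam_records()].
#' @export
simulate_alignments <- function(sim, truth, mapq = 60L, min_anchor = 20L) {
  stopifnot(length(unique(truth$set_id)) == 1L)
  reads <- sim$reads
  rl <- sim$read_len
  tr <- truth[order(truth$genome_start, truth$genome_end), , drop = FALSE]
  n <- nrow(reads)
  # find, for each read, the truth segment with the largest overlap
  res <- data.frame(contig_id = NA_character_, start = NA_integer_,
                    clip_l = 0L, clip_r = 0L, stringsAsFactors = FALSE)[rep(1L, n), ]
  rownames(res) <- NULL
  gs <- reads$genome_start; ge <- reads$genome_end
  # candidate segments via interval walk (segments may overlap when the
  # genome region is present in several contigs; first hit wins)
  best_ov <- rep(0L, n)
  for (si in seq_len(nrow(tr))) {
    a <- pmax(gs, tr$genome_start[si]); b <- pmin(ge, tr$genome_end[si])
    ov <- pmax(0L, b - a)
    upd <- ov > best_ov
    if (!any(upd)) next
    best_ov[upd] <- ov[upd]
    res$contig_id[upd] <- tr$contig_id[si]
    res$clip_l[upd] <- (a - gs)[upd]
    res$clip_r[upd] <- (ge - b)[upd]
    res$start[upd] <- (tr$contig_start[si] + (a - tr$genome_start[si]))[upd]
  }
  mapped <- !is.na(res$contig_id) & best_ov >= min_anchor
  # orientation on the contig equals genome orientation (segments are +)
  is_rev <- reads$strand == "-"
  m_len <- rl - res$clip_l - res$clip_r
  # clips are in genome orientation; CIGAR is written in read orientation
  lead <- ifelse(is_rev, res$clip_r, res$clip_l)
  trail <- ifelse(is_rev, res$clip_l, res$clip_r)
  cig <- paste0(ifelse(lead > 0L, paste0(lead, "S"), ""),
                m_len, "M",
                ifelse(trail > 0L, paste0(trail, "S"), ""))
  mean_bq <- vapply(unique(reads$qual), function(q) {
    mean(as.integer(charToRaw(q)) - 33L)
  }, numeric(1))
  rec <- data.frame(
    read_id = reads$read_id, mate = reads$mate, contig_id = res$contig_id,
    start = res$start, cigar = cig, mapq = mapq,
    ref_span = m_len, query_len = rl,
    mean_bq = unname(mean_bq[reads$qual]), is_reverse = is_rev,
    mate_contig_id = NA_character_, stringsAsFactors = FALSE)[mapped, , drop = FALSE]
  # mate contig from the other end of each pair
  key <- paste(rec$read_id, 3L - rec$mate)
  self <- paste(rec$read_id, rec$mate)
  rec$mate_contig_id <- rec$contig_id[match(key, self)]
  rownames(rec) <- NULL
  rec
}

#' Write alignment records as a SAM file
#'
#' @param records alignment records.
#' @param set the `contig_set` the records refer to (for the header).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(records, set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  lens <- contig_lengths(set)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(records)) {
    flag <- ifelse(records$mate == 2L, 128L, 64L) + 1L +
      ifelse(records$is_reverse, 16L, 0L) +
      ifelse(is.na(records$mate_contig_id), 8L, 0L)
    rnext <- ifelse(is.na(records$mate_contig_id), "*",
                    ifelse(records$mate_contig_id == records$contig_id, "=",
                           records$mate_contig_id))
    writeLines(paste(records$read_id, flag, records$contig_id,
                     records$start + 1L, records$mapq, records$cigar,
                     rnext, 0L, 0L, "*", "*", sep = "\t"), con)
  }
  invisible(path)
}

#' Exact block matcher between two contig sets
#'
#' Finds maximal exact matches of at least `min_len` bases between the two
#' sets on both strands, by k-mer anchoring and diagonal run detection. A
#' deliberately simple stand-in for an external whole-genome aligner, meant
#' for assemblies of the same genome where shared segments are exact.
#'
#' @param o_set,r_set the two `contig_set`s.
#' @param min_len minimum match length (default 200).
#' @param k k-mer size (default 31).
#' @return block matches in the format of [parse_coords_table()]
#'   (identity = 1).
#' @export
match_blocks <- function(o_set, r_set, min_len = 200L, k = 31L) {
  kmers_of <- function(seqs) {
    out <- list()
    for (cid in names(seqs)) {
      s <- seqs[[cid]]
      L <- nchar(s)
      if (L < k) next
      n <- L - k + 1L
      out[[cid]] <- data.table::data.table(
        kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
        pos = seq_len(n) - 1L, contig = cid)
    }
    data.table::rbindlist(out)
  }
  r_idx <- kmers_of(r_set$contigs)
  if (!nrow(r_idx)) return(empty_block_matches())
  out <- list()
  for (strand in c(TRUE, FALSE)) {
    o_seqs <- if (strand) o_set$contigs else
      stats::setNames(revcomp(o_set$contigs), names(o_set$contigs))
    o_idx <- kmers_of(o_seqs)
    if (!nrow(o_idx)) next
    hits <- merge(o_idx, r_idx, by = "kmer", allow.cartesian = TRUE,
                  suffixes = c("_o", "_r"))
    if (!nrow(hits)) next
    hits[, diag := pos_r - pos_o]
    data.table::setorder(hits, contig_o, contig_r, diag, pos_o)
    # runs of consecutive k-mer hits along one diagonal
    brk <- c(TRUE, hits$contig_o[-1L] != hits$contig_o[-nrow(hits)] |
               hits$contig_r[-1L] != hits$contig_r[-nrow(hits)] |
               hits$diag[-1L] != hits$diag[-nrow(hits)] |
               hits$pos_o[-1L] != hits$pos_o[-nrow(hits)] + 1L)
    grp <- cumsum(brk)
    runs <- hits[, .(o_start = min(pos_o), o_end = max(pos_o) + k,
                     r_start = min(pos_r), r_end = max(pos_r) + k,
                     contig_o = contig_o[1L], contig_r = contig_r[1L]),
                 by = .(g = grp)]
    runs <- runs[o_end - o_start >= min_len]
    if (!nrow(runs)) next
    if (!strand) {
      # map O coordinates back to the forward strand
      o_lens <- nchar(o_set$contigs)[runs$contig_o]
      new_start <- o_lens - runs$o_end
      runs$o_end <- o_lens - runs$o_start
      runs$o_start <- new_start
    }
    out[[length(out) + 1L]] <- data.frame(
      o_contig = runs$contig_o, o_start = runs$o_start, o_end = runs$o_end,
      r_contig = runs$contig_r, r_start = runs$r_start, r_end = runs$r_end,
      same_strand = strand, identity = 1, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_block_matches())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The canonical nine-block worked example
#'
#' Two contig sets sharing nine consensus blocks, arranged as
#' O = \{[1,5], [9], [8,2], [-3,7], [6,4]\} and
#' R = \{[1,6,5], [4,3,9], [2,7,8]\}, with an uncertain position between
#' blocks 1 and 5 of O's first contig (a repeat-mediated misjoin: the heads
#' of blocks 1 and 6 share a repeat) and between blocks 7 and 8 of R's third
#' contig. With `materialize = TRUE` the blocks are realized as concrete
#' 1 kb sequences (with a shared 300 bp repeat at the heads of blocks 1
#' and 6) and the contig sets returned alongside the chains.
#'
#' @param materialize also build concrete sequences (default FALSE).
#' @param block_len block length when materializing (default 1000).
#' @param repeat_len shared repeat length (default 300).
#' @param seed RNG seed for the materialized sequences.
#' @return list with `o_chains`, `r_chains` (chain lists with error marks),
#'   `classification` (per-contig marks), and when materialized: `o_set`,
#'   `r_set`, `block_sequences`, `label_of` (function mapping a found block
#'   placement to the canonical label), `paper_sign` (orientation of each
#'   labeled block in O).
#' @export
figure2_fixture <- function(materialize = FALSE, block_len = 1000L,
                            repeat_len = 300L, seed = 7L) {
  o_layout <- list(oc1 = c(1, 5), oc2 = c(9), oc3 = c(8, 2),
                   oc4 = c(-3, 7), oc5 = c(6, 4))
  r_layout <- list(rc1 = c(1, 6, 5), rc2 = c(4, 3, 9), rc3 = c(2, 7, 8))
  mk <- function(layout, tag) {
    lapply(names(layout), function(cid) {
      b <- layout[[cid]]
      starts <- (seq_along(b) - 1L) * block_len
      new_chain(cid, tag, b, starts, starts + block_len)
    })
  }
  o_chains <- mk(o_layout, "O")
  r_chains <- mk(r_layout, "R")
  # uncertain positions: between blocks 1 and 5 of oc1; between 7 and 8 of rc3
  o_chains[[1]]$errs <- 1L
  r_chains[[3]]$errs <- 2L
  classification <- list(
    o = list(oc1 = list(contig_id = "oc1", label = "U",
                        error_positions = block_len,
                        source_contig = "oc1", source_offset = 0L)),
    r = list(rc3 = list(contig_id = "rc3", label = "U",
                        error_positions = 2L * block_len,
                        source_contig = "rc3", source_offset = 0L)))
  out <- list(o_chains = o_chains, r_chains = r_chains,
              classification = classification)
  if (!materialize) return(out)
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")
  blocks <- lapply(1:9, function(i) {
    paste(sample(bases, block_len, replace = TRUE), collapse = "")
  })
  # heads of blocks 1 and 6 share a repeat (the misjoin mechanism)
  substr(blocks[[6]], 1L, repeat_len) <- substr(blocks[[1]], 1L, repeat_len)
  assemble <- function(layout) {
    seqs <- vapply(layout, function(b) {
      paste(vapply(b, function(x) {
        if (x > 0) blocks[[x]] else revcomp(blocks[[-x]])
      }, character(1)), collapse = "")
    }, character(1))
    seqs
  }
  o_set <- contig_set(assemble(o_layout), set_id = "O")
  r_set <- contig_set(assemble(r_layout), set_id = "R")
  # placements of each labeled block in O, for mapping found blocks to labels
  placements <- list()
  for (cid in names(o_layout)) {
    b <- o_layout[[cid]]
    for (i in seq_along(b)) {
      placements[[as.character(abs(b[i]))]] <- list(
        contig = cid, start = (i - 1L) * block_len, end = i * block_len,
        sign = sign(b[i]))
    }
  }
  label_of <- function(o_contig, o_start, o_end) {
    for (lab in names(placements)) {
      p <- placements[[lab]]
      if (p$contig == o_contig && o_start < p$end && o_end > p$start) {
        return(as.integer(lab))
      }
    }
    NA_integer_
  }
  paper_sign <- vapply(as.character(1:9),
                       function(lab) placements[[lab]]$sign, numeric(1))
  c(out, list(o_set = o_set, r_set = r_set, block_sequences = blocks,
              label_of = label_of, paper_sign = paper_sign))
}

#' Random two-set chain instance
#'
#' Random signed arrangements of `n_blocks` blocks, independently cut into
#' chains for each set; used for oracle comparisons of the graph algebra.
#'
#' @param n_blocks number of blocks (each present once per set).
#' @param seed RNG seed.
#' @param max_chains maximum chains per set (default 4).
#' @return list with `o_chains` and `r_chains`.
#' @export
random_chain_instance <- function(n_blocks, seed = 1L, max_chains = 4L) {
  rng <- local_rng(seed)
  mk <- function(tag) {
    perm <- sample.int(n_blocks) * sample(c(-1L, 1L), n_blocks, replace = TRUE)
    n_ch <- sample.int(min(max_chains, n_blocks), 1L)
    cuts <- if (n_ch > 1L) sort(sample(seq_len(n_blocks - 1L), n_ch - 1L)) else integer(0)
    bounds <- c(0L, cuts, n_blocks)
    lapply(seq_len(length(bounds) - 1L), function(i) {
      sel <- (bounds[i] + 1L):bounds[i + 1L]
      new_chain(sprintf("%s%d", tolower(tag), i), tag, perm[sel])
    })
  }
  list(o_chains = mk("O"), r_chains = mk("R"))
}
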