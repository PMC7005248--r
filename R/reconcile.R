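# Reconciliation: the iterative optimization loop over the adjacent graph
# (fuse good paths, resolve poor paths by classification-driven splitting,
# rebuild), overlap merging of the resulting chains, base-level emission
# with provenance, and the pairwise/multi-assembly orchestration.

#' Default reconciliation configuration
#'
#' @param alpha coverage cutoff factor for candidate regions (default 0.5).
#' @param beta mate-support rate threshold (default 0.8).
#' @param min_block minimum consensus block length in bases (default 200).
#' @param min_identity minimum block match identity (default 0.95).
#' @param g_max maximum gap between adjacent blocks in bases (default 10).
#' @param flank flank width in bases for mate support, GC windows and error
#'   carrying; NULL means "use the fitted insert-size mean" (default NULL).
#' @param min_fragment minimum contig fragment length kept after splitting
#'   (default 200).
#' @param edge_trim contig-end positions excluded from candidate detection;
#'   NULL means "one insert-size mean" — pair geometry suppresses coverage
#'   within an insert of a contig end (default NULL).
#' @param max_iter maximum merge iterations; NULL means "number of blocks".
#' @param kmer k-mer size of the internal block matcher (default 31).
#' @return a named list of settings.
#' @export
reconcile_config <- function(alpha = 0.5, beta = 0.8, min_block = 200L,
                             min_identity = 0.95, g_max = 10L, flank = NULL,
                             min_fragment = 200L, edge_trim = NULL,
                             max_iter = NULL, kmer = 31L) {
  list(alpha = alpha, beta = beta, min_block = min_block,
       min_identity = min_identity, g_max = g_max, flank = flank,
       min_fragment = min_fragment, edge_trim = edge_trim,
       max_iter = max_iter, kmer = kmer)
}

#' Create a merge state
#'
#' @param o_chains,r_chains chain lists of the two sets.
#' @return a `merge_state`.
#' @export
merge_state <- function(o_chains, r_chains) {
  structure(list(o_chains = o_chains, r_chains = r_chains,
                 iteration = 0L, converged = FALSE,
                 distances = numeric(0),
                 log = data.frame(iteration = integer(0), event = character(0),
                                  detail = character(0),
                                  stringsAsFactors = FALSE)),
            class = "merge_state")
}

log_event <- function(state, event, detail) {
  state$log <- rbind(state$log, data.frame(
    iteration = state$iteration, event = event, detail = detail,
    stringsAsFactors = FALSE))
  state
}

# split one chain at the given adjacency indices (errors between blocks
# i and i+1); consumed error positions are removed
split_chain_at <- function(ch, at) {
  at <- sort(unique(at))
  bounds <- c(0L, at, length(ch$blocks))
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    sel <- (bounds[k] + 1L):bounds[k + 1L]
    errs <- ch$errs[ch$errs > bounds[k] & ch$errs < bounds[k + 1L]] - bounds[k]
    out[[k]] <- new_chain(paste0(ch$id, "|", k), ch$set_tag, ch$blocks[sel],
                          ch$starts[sel], ch$ends[sel], errs)
  }
  out
}

#' Resolve poor paths
#'
#' Non-single poor-1 paths: every chain the path traverses that still carries
#' an error position in an adjacent region (a U contig) is split there.
#' Single poor-1 paths and circles are left alone. A poor-2 path whose both
#' end terminals occur in some good path is removed together with the chain
#' containing it; otherwise it is retained.
#'
#' @param state a `merge_state`.
#' @param paths path records from [extract_paths()] on the state's graph.
#' @param vertices optionally, the vertex table of that graph (recomputed
#'   from the state when omitted).
#' @return the updated state, with `n_splits` and `n_removed` attributes in
#'   `state$last_resolution`.
#' @export
resolve_poor_paths <- function(state, paths, vertices = NULL) {
  if (is.null(vertices)) {
    vertices <- build_graph(state$o_chains, state$r_chains)$vertices
  }
  good_terms <- unique(unlist(lapply(
    paths[vapply(paths, `[[`, character(1), "ptype") == "good"],
    function(p) p$labels)))
  good_terms <- unique(unlist(regmatches(good_terms,
                                         gregexpr("[0-9]+[th]", good_terms))))
  n_splits <- 0L; n_removed <- 0L
  split_targets <- list(O = integer(0), R = integer(0))
  remove_targets <- list(O = integer(0), R = integer(0))
  for (p in paths) {
    if (p$ptype == "poor1_nonsingle") {
      # chains traversed by the path, per set
      for (vid in p$vids) {
        tag <- vertices$set_tag[vid]; ci <- vertices$chain_idx[vid]
        split_targets[[tag]] <- union(split_targets[[tag]], ci)
      }
    } else if (p$ptype == "poor2") {
      ends_in_good <- all(p$end_terminals %in% good_terms)
      if (ends_in_good) {
        tag <- p$end_sets[1L]
        remove_targets[[tag]] <- union(remove_targets[[tag]], p$end_chains[1L])
      }
    }
  }
  for (tag in c("O", "R")) {
    fld <- if (tag == "O") "o_chains" else "r_chains"
    chains <- state[[fld]]
    # removals first (indices refer to the current lists)
    rm_idx <- remove_targets[[tag]]
    sp_idx <- setdiff(split_targets[[tag]], rm_idx)
    new_chains <- list()
    for (ci in seq_along(chains)) {
      if (ci %in% rm_idx) {
        n_removed <- n_removed + 1L
        state <- log_event(state, "remove_chain",
                           paste0(tag, ":", chains[[ci]]$id))
        next
      }
      if (ci %in% sp_idx && length(chains[[ci]]$errs)) {
        pieces <- split_chain_at(chains[[ci]], chains[[ci]]$errs)
        n_splits <- n_splits + length(pieces) - 1L
        state <- log_event(state, "split_chain",
                           paste0(tag, ":", chains[[ci]]$id, " at ",
                                  paste(chains[[ci]]$errs, collapse = ",")))
        new_chains <- c(new_chains, pieces)
      } else {
        new_chains <- c(new_chains, list(chains[[ci]]))
      }
    }
    state[[fld]] <- new_chains
  }
  state$last_resolution <- list(n_splits = n_splits, n_removed = n_removed)
  state
}

#' Run the merge loop to convergence
#'
#' Repeats extract paths, fuse good paths, resolve poor paths, and rebuild
#' the graph, until an iteration adds no good path and performs no split or
#' removal, or `max_iter` is reached. The block-count algebraic distance is
#' recorded before each iteration and after convergence.
#'
#' @param state a `merge_state`.
#' @param max_iter iteration cap; defaults to the number of distinct blocks.
#' @return the converged state; `state$converged` is FALSE when the cap was
#'   hit.
#' @export
iterate_merge <- function(state, max_iter = NULL) {
  n_blocks <- length(unique(abs(c(
    unlist(lapply(state$o_chains, `[[`, "blocks")),
    unlist(lapply(state$r_chains, `[[`, "blocks"))))))
  if (is.null(max_iter)) max_iter <- max(n_blocks, 1L)
  repeat {
    g <- build_graph(state$o_chains, state$r_chains)
    paths <- extract_paths(g)
    state$distances <- c(state$distances, algebraic_distance(g, paths)$d_blocks)
    ptypes <- vapply(paths, `[[`, character(1), "ptype")
    good <- paths[ptypes == "good"]
    state$iteration <- state$iteration + 1L
    # resolve poor paths first (chain indices refer to this graph), then fuse
    state <- resolve_poor_paths(state, paths, g$vertices)
    n_fused <- 0L
    for (tag in c("O", "R")) {
      gp <- good[vapply(good, function(p) identical(p$end_set, tag), logical(1))]
      if (!length(gp)) next
      fld <- if (tag == "O") "o_chains" else "r_chains"
      res <- fuse_good_paths(state[[fld]], gp)
      state[[fld]] <- res$chains
      n_fused <- n_fused + res$fused
      if (res$skipped) {
        state <- log_event(state, "fusion_skipped",
                           paste0(tag, ": ", res$skipped, " conflicting"))
      }
    }
    state <- log_event(state, "iteration_summary",
                       sprintf("good=%d fused=%d splits=%d removed=%d",
                               length(good), n_fused,
                               state$last_resolution$n_splits,
                               state$last_resolution$n_removed))
    done <- length(good) == 0L && state$last_resolution$n_splits == 0L &&
      state$last_resolution$n_removed == 0L
    if (done) { state$converged <- TRUE; break }
    if (state$iteration >= max_iter) {
      warning("merge loop did not converge within ", max_iter, " iterations")
      break
    }
  }
  g <- build_graph(state$o_chains, state$r_chains)
  state$distances <- c(state$distances, algebraic_distance(g)$d_blocks)
  state
}

#' Merge overlapping chains
#'
#' Pools chains and absorbs shorter ones into longer ones: a shorter chain
#' whose entire block content already occurs in a longer chain is dropped; a
#' shorter chain sharing a prefix or suffix of at least two blocks with a
#' longer chain (after orientation normalization) is spliced in, repeating
#' the last shared block (the repeat copy re-entry).
#'
#' @param chains list of `adjacency_chain` objects (any set tags).
#' @return list with `chains` (merged, canonicalized) and `absorbed`
#'   (data.frame of absorption events).
#' @export
merge_overlapping_chains <- function(chains) {
  if (!length(chains)) return(list(chains = chains, absorbed = NULL))
  ord <- order(-vapply(chains, function(ch) length(ch$blocks), integer(1)))
  events <- list()
  result <- list()
  for (i in ord) {
    ch <- chains[[i]]
    placed <- FALSE
    for (j in seq_along(result)) {
      m <- absorb_chain(result[[j]], ch)
      if (!is.null(m)) {
        events[[length(events) + 1L]] <- data.frame(
          absorbed = ch$id, into = result[[j]]$id, mode = m$mode,
          stringsAsFactors = FALSE)
        result[[j]] <- m$chain
        placed <- TRUE
        break
      }
    }
    if (!placed) result <- c(result, list(ch))
  }
  result <- lapply(result, canonicalize_chain)
  list(chains = result,
       absorbed = if (length(events)) do.call(rbind, events) else NULL)
}

# try to absorb `shorter` into `longer`; returns list(chain, mode) or NULL
absorb_chain <- function(longer, shorter) {
  if (length(shorter$blocks) > length(longer$blocks)) return(NULL)
  if (all(abs(shorter$blocks) %in% abs(longer$blocks))) {
    return(list(chain = longer, mode = "contained"))
  }
  for (sh in list(shorter, revneg_chain(shorter))) {
    spl <- splice_prefix(longer, sh)
    if (!is.null(spl)) return(list(chain = spl, mode = "prefix_splice"))
    # suffix overlap: reverse both, splice, reverse back
    spl <- splice_prefix(revneg_chain(longer), revneg_chain(sh))
    if (!is.null(spl)) {
      return(list(chain = revneg_chain(spl), mode = "suffix_splice"))
    }
  }
  NULL
}

# shared-prefix splice: shorter = p ++ tail, longer = p ++ rest, |p| >= 2
# -> p ++ tail ++ (last block of p) ++ rest, i.e. shorter ++ longer[|p|..]
splice_prefix <- function(longer, shorter) {
  a <- shorter$blocks; b <- longer$blocks
  k <- 0L
  while (k < length(a) && k < length(b) && a[k + 1L] == b[k + 1L]) k <- k + 1L
  if (k < 2L || k == length(a)) return(NULL)
  new_chain(paste0(longer$id, "~", shorter$id), longer$set_tag,
            c(a, b[k:length(b)]),
            c(shorter$starts, longer$starts[k:length(b)]),
            c(shorter$ends, longer$ends[k:length(b)]))
}

# spacer lookup from the original (pre-fusion) per-contig chains: for each
# consecutive block pair, the inter-block sequence on the source contig
build_spacer_table <- function(chains, set, set_tag) {
  tab <- list()
  for (ch in chains) {
    b <- ch$blocks
    if (length(b) < 2L) next
    seqc <- set$contigs[[sub("/.*$", "", ch$id)]]
    for (i in seq_len(length(b) - 1L)) {
      gap <- ch$starts[i + 1L] - ch$ends[i]
      spacer <- if (!is.na(gap) && gap > 0) {
        substr(seqc, ch$ends[i] + 1L, ch$starts[i + 1L])
      } else ""
      key <- paste(b[i], b[i + 1L], sep = "|")
      if (is.null(tab[[key]])) {
        tab[[key]] <- list(seq = spacer, gap = if (is.na(gap)) 0 else gap,
                           source_set = set_tag,
                           source_contig = sub("/.*$", "", ch$id),
                           source_start = ch$ends[i],
                           source_end = ch$starts[i + 1L], strand = "+")
      }
    }
  }
  tab
}

#' Emit merged sequences from final chains
#'
#' Block sequences come from the higher-ranked set's placements
#' (reverse-complemented for negative signs); inter-block spacers come from
#' whichever source contig supplied that adjacency (empty for adjacencies
#' created by fusion). Negative source gaps (end-to-end overlaps) trim the
#' incoming block. Blockless contigs of both sets are appended verbatim.
#' Every emitted base is recorded in a provenance table.
#'
#' @param final_chains merged chain list.
#' @param blocks consensus block table.
#' @param o_set,r_set the two (post-classification) contig sets; O outranks R.
#' @param o_chains0,r_chains0 the original pre-fusion chain lists (spacer
#'   sources).
#' @return a `merged_assembly`: `set` (contig_set), `chains`, `provenance`.
#' @export
emit_sequences <- function(final_chains, blocks, o_set, r_set,
                           o_chains0, r_chains0) {
  spacers <- c(build_spacer_table(o_chains0, o_set, "O"),
               build_spacer_table(r_chains0, r_set, "R"))
  block_seq <- function(bid) {
    row <- blocks[blocks$block_id == bid, , drop = FALSE]
    if (!nrow(row)) stop("internal consistency error: no placement for block ", bid)
    substr(o_set$contigs[[row$o_contig]], row$o_start + 1L, row$o_end)
  }
  seqs <- character(0)
  prov <- list()
  add_prov <- function(out_contig, out_start, out_end, source_set,
                       source_contig, source_start, source_end, strand) {
    prov[[length(prov) + 1L]] <<- data.frame(
      out_contig = out_contig, out_start = out_start, out_end = out_end,
      source_set = source_set, source_contig = source_contig,
      source_start = source_start, source_end = source_end, strand = strand,
      stringsAsFactors = FALSE)
  }
  out_chains <- list()
  for (ci in seq_along(final_chains)) {
    ch <- final_chains[[ci]]
    name <- sprintf("merged_%d", ci)
    ch$id <- name
    out_chains[[ci]] <- ch
    cur <- ""
    b <- ch$blocks
    for (i in seq_along(b)) {
      trim <- 0L
      if (i > 1L) {
        key <- paste(b[i - 1L], b[i], sep = "|")
        rkey <- paste(-b[i], -b[i - 1L], sep = "|")
        sp <- spacers[[key]]
        rc <- FALSE
        if (is.null(sp)) { sp <- spacers[[rkey]]; rc <- TRUE }
        if (!is.null(sp)) {
          if (sp$gap < 0) trim <- -sp$gap
          if (nzchar(sp$seq)) {
            s <- if (rc) revcomp(sp$seq) else sp$seq
            add_prov(name, nchar(cur), nchar(cur) + nchar(s), sp$source_set,
                     sp$source_contig, sp$source_start, sp$source_end,
                     if (rc) "-" else "+")
            cur <- paste0(cur, s)
          }
        }
      }
      s <- block_seq(abs(b[i]))
      if (b[i] < 0) s <- revcomp(s)
      if (trim > 0L) s <- substr(s, trim + 1L, nchar(s))
      row <- blocks[blocks$block_id == abs(b[i]), ]
      add_prov(name, nchar(cur), nchar(cur) + nchar(s), "O", row$o_contig,
               row$o_start + trim, row$o_end, if (b[i] > 0) "+" else "-")
      cur <- paste0(cur, s)
    }
    seqs[[name]] <- cur
  }
  # blockless contigs pass through verbatim
  for (tag in c("O", "R")) {
    set <- if (tag == "O") o_set else r_set
    placed <- unique(if (tag == "O") blocks$o_contig else blocks$r_contig)
    for (cid in setdiff(names(set$contigs), placed)) {
      name <- paste0(set$set_id, "_", cid)
      seqs[[name]] <- set$contigs[[cid]]
      add_prov(name, 0L, nchar(seqs[[name]]), tag, cid, 0L,
               nchar(seqs[[name]]), "+")
    }
  }
  structure(list(
    set = contig_set(seqs, set_id = paste0(o_set$set_id, "+", r_set$set_id)),
    chains = out_chains,
    provenance = do.call(rbind, prov)), class = "merged_assembly")
}

#' @export
print.merged_assembly <- function(x, ...) {
  cat("<merged_assembly>\n")
  print(x$set)
  invisible(x)
}
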