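# Pairwise and multi-assembly orchestration: preprocessing, classification,
# block identification, the graph merge loop, overlap merging and emission.

# remap externally supplied block matches through classification splits:
# each match interval is intersected with the fragment intervals of the
# split contig; pieces shorter than min_len are dropped
remap_matches_through_splits <- function(matches, classification, side,
                                         min_len, split_set) {
  if (!nrow(matches)) return(matches)
  frag <- do.call(rbind, lapply(classification, function(cl) {
    data.frame(frag = cl$contig_id, src = cl$source_contig,
               off = cl$source_offset, stringsAsFactors = FALSE)
  }))
  frag$len <- nchar(split_set$contigs[frag$frag])
  ctg_col <- paste0(side, "_contig")
  s_col <- paste0(side, "_start"); e_col <- paste0(side, "_end")
  out <- list()
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, , drop = FALSE]
    fr <- frag[frag$src == m[[ctg_col]], , drop = FALSE]
    if (!nrow(fr)) next
    for (k in seq_len(nrow(fr))) {
      # intersect the match with this fragment's interval on the source
      # contig (0-based half-open), then shift to fragment coordinates
      a <- max(m[[s_col]], fr$off[k])
      b <- min(m[[e_col]], fr$off[k] + fr$len[k])
      if (b - a < min_len) next
      piece <- m
      piece[[ctg_col]] <- fr$frag[k]
      piece[[s_col]] <- a - fr$off[k]
      piece[[e_col]] <- b - fr$off[k]
      out[[length(out) + 1L]] <- piece
    }
  }
  if (!length(out)) return(matches[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Merge two assemblies
#'
#' Runs the full pairwise pipeline: (optional) alignment preprocessing and
#' contig classification, consensus block identification, adjacency chains,
#' the iterative graph merge, overlap merging, and sequence emission.
#' `o_set` must be the higher-ranked assembly.
#'
#' @param o_set,r_set the two `contig_set`s; O outranks R.
#' @param o_records,r_records raw alignment records per set (optional; when
#'   given they drive classification).
#' @param matches precomputed block matches (optional; when omitted the
#'   internal exact matcher is used).
#' @param classification optional list with elements `o` and `r`: precomputed
#'   per-contig classification (as produced by [classify_and_break()]),
#'   overriding alignment-driven classification.
#' @param config settings from [reconcile_config()].
#' @return a `merged_assembly`; also carries `state`, `blocks`,
#'   `classification` and `ranking` fields.
#' @export
merge_pair <- function(o_set, r_set, o_records = NULL, r_records = NULL,
                       matches = NULL, classification = NULL,
                       config = reconcile_config()) {
  cls <- list(o = NULL, r = NULL)
  sets <- list(o = o_set, r = r_set)
  recs <- list(o = o_records, r = r_records)
  for (side in c("o", "r")) {
    if (!is.null(classification[[side]])) {
      cls[[side]] <- classification[[side]]
    } else if (!is.null(recs[[side]])) {
      pp <- preprocess_alignments(recs[[side]])
      flank <- config$flank
      if (is.null(flank)) {
        flank <- if (!is.null(pp$insert_model)) round(pp$insert_model$mu_is) else 300L
      }
      # coverage is suppressed within one insert length of a contig end by
      # pair geometry alone, so candidate detection skips that margin
      edge_trim <- config$edge_trim
      if (is.null(edge_trim)) edge_trim <- flank
      cb <- classify_and_break(sets[[side]], pp$records, alpha = config$alpha,
                               beta = config$beta, flank = flank,
                               min_fragment = config$min_fragment,
                               edge_trim = edge_trim)
      sets[[side]] <- cb$set
      cls[[side]] <- cb$classification
      if (!is.null(matches)) {
        matches <- remap_matches_through_splits(matches, cb$classification,
                                                side, config$min_block, cb$set)
      }
    }
  }
  if (is.null(matches)) {
    matches <- match_blocks(sets$o, sets$r, min_len = config$min_block,
                            k = config$kmer)
  }
  blocks <- find_consensus_blocks(matches, sets$o, sets$r,
                                  min_len = config$min_block,
                                  min_identity = config$min_identity)
  if (!nrow(blocks)) {
    warning("no consensus blocks found; returning the higher-ranked set")
    out <- structure(list(set = sets$o, chains = list(),
                          provenance = data.frame()),
                     class = "merged_assembly")
    out$blocks <- blocks
    return(out)
  }
  flank_carry <- if (is.null(config$flank)) 100L else config$flank
  mk_chains <- function(set, tag, clz) {
    chains <- build_adjacency_chains(set, blocks, set_tag = tag,
                                     g_max = config$g_max)
    lapply(chains, function(ch) {
      carry_error_positions(ch, clz[[sub("/.*$", "", ch$id)]],
                            flank = flank_carry)
    })
  }
  o_chains0 <- mk_chains(sets$o, "O", cls$o)
  r_chains0 <- mk_chains(sets$r, "R", cls$r)
  state <- merge_state(o_chains0, r_chains0)
  state <- iterate_merge(state, max_iter = config$max_iter)
  pooled <- merge_overlapping_chains(c(state$o_chains, state$r_chains))
  merged <- emit_sequences(pooled$chains, blocks, sets$o, sets$r,
                           o_chains0, r_chains0)
  merged$state <- state
  merged$blocks <- blocks
  merged$classification <- cls
  merged$absorbed <- pooled$absorbed
  merged
}

# lift classification (error positions of U contigs) of the inputs through
# the provenance of a merged assembly, giving a classification for the
# merged contigs without re-alignment
lift_classification <- function(merged, cls_by_set) {
  if (is.null(merged$provenance) || !nrow(merged$provenance)) return(list())
  out <- list()
  prov <- merged$provenance
  for (i in seq_len(nrow(prov))) {
    tag <- tolower(prov$source_set[i])
    cl <- cls_by_set[[tag]][[prov$source_contig[i]]]
    if (is.null(cl) || cl$label != "U" || !length(cl$error_positions)) next
    p <- cl$error_positions
    inside <- p > prov$source_start[i] & p <= prov$source_end[i]
    if (!any(inside)) next
    p <- p[inside]
    mapped <- if (prov$strand[i] == "+") {
      prov$out_start[i] + (p - prov$source_start[i])
    } else {
      prov$out_start[i] + (prov$source_end[i] - p + 1L)
    }
    oc <- prov$out_contig[i]
    if (is.null(out[[oc]])) {
      out[[oc]] <- list(contig_id = oc, label = "U",
                        error_positions = integer(0),
                        source_contig = oc, source_offset = 0L)
    }
    out[[oc]]$error_positions <- sort(unique(c(out[[oc]]$error_positions,
                                               as.integer(mapped))))
  }
  out
}

#' Merge two or more assemblies
#'
#' Assemblies are ranked by [assembly_score()] (descending) and merged
#' pairwise, folding left to right: the current result is merged with the
#' next assembly in rank order. Classification of intermediate results is
#' lifted through provenance rather than re-aligned.
#'
#' @param sets list of `contig_set`s (at least two).
#' @param records_list list of raw alignment records, parallel to `sets`
#'   (optional; without it the input order is used as the ranking and
#'   classification is skipped).
#' @param config settings from [reconcile_config()].
#' @return a `merged_assembly`; `ranking` holds the merge order used.
#' @export
merge_all <- function(sets, records_list = NULL, config = reconcile_config()) {
  if (length(sets) < 2L) stop("merging needs at least two assemblies")
  ids <- vapply(sets, `[[`, character(1), "set_id")
  if (anyDuplicated(ids)) stop("assembly set_ids must be unique")
  if (!is.null(records_list)) {
    stopifnot(length(records_list) == length(sets))
    pp <- lapply(records_list, preprocess_alignments)
    scores <- lapply(seq_along(sets), function(i) {
      assembly_score(sets[[i]], pp[[i]]$records)
    })
    order_ids <- rank_assemblies(scores)
  } else {
    scores <- NULL
    order_ids <- ids
  }
  ord <- match(order_ids, ids)
  cur_set <- sets[[ord[1L]]]
  cur_records <- if (!is.null(records_list)) records_list[[ord[1L]]] else NULL
  cur_cls <- NULL
  merged <- NULL
  for (k in ord[-1L]) {
    merged <- merge_pair(cur_set, sets[[k]],
                         o_records = cur_records,
                         r_records = if (!is.null(records_list)) records_list[[k]] else NULL,
                         classification = if (!is.null(cur_cls)) list(o = cur_cls) else NULL,
                         config = config)
    cur_cls <- lift_classification(merged, merged$classification)
    cur_set <- merged$set
    cur_records <- NULL  # no re-alignment; classification is lifted
  }
  merged$ranking <- order_ids
  merged$scores <- scores
  merged
}
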