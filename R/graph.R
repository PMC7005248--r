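# The adjacent graph. Vertices are block terminals ("5t"/"5h") or
# conjunctions of two terminals (the junction inside a chain); an edge joins
# an O vertex and an R vertex sharing a terminal. Since every terminal occurs
# at most once per set, vertex degree is bounded by the number of terminals
# it holds, and the edge set decomposes uniquely into maximal paths and
# cycles. Good paths (even length, ends in the same set but different
# adjacencies) are closed into cycles, fusing two chains into a longer one.

terminal_entry <- function(b) paste0(abs(b), if (b > 0) "t" else "h")
terminal_exit <- function(b) paste0(abs(b), if (b > 0) "h" else "t")

# vertex table of one chain set; chain_idx indexes into the chains list
chain_vertices <- function(chains, set_tag) {
  rows <- list()
  for (ci in seq_along(chains)) {
    b <- chains[[ci]]$blocks
    k <- length(b)
    ts <- character(0); t2 <- character(0)
    # single terminals at the two chain ends
    rows[[length(rows) + 1L]] <- data.frame(
      set_tag = set_tag, t1 = terminal_entry(b[1L]), t2 = NA_character_,
      chain_idx = ci, slot = 0L, stringsAsFactors = FALSE)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          set_tag = set_tag, t1 = terminal_exit(b[i]),
          t2 = terminal_entry(b[i + 1L]), chain_idx = ci, slot = i,
          stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      set_tag = set_tag, t1 = terminal_exit(b[k]), t2 = NA_character_,
      chain_idx = ci, slot = k, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build the adjacent graph over two chain sets
#'
#' @param o_chains,r_chains lists of `adjacency_chain` objects from the two
#'   sets, over a shared block numbering.
#' @return an `adjacent_graph`: vertex table (set_tag, t1, t2, chain_idx,
#'   slot), edge table (v_o, v_r, terminal), and the chain lists.
#' @export
build_graph <- function(o_chains, r_chains) {
  vo <- chain_vertices(o_chains, "O")
  vr <- chain_vertices(r_chains, "R")
  v <- rbind(vo, vr)
  v$vid <- seq_len(nrow(v))
  for (tag in c("O", "R")) {
    terms <- c(v$t1[v$set_tag == tag], v$t2[v$set_tag == tag])
    terms <- terms[!is.na(terms)]
    if (anyDuplicated(terms)) {
      stop("terminal ", terms[duplicated(terms)][1L],
           " occurs twice in set ", tag, ": block id repeated within one set")
    }
  }
  # terminal -> vid maps per set
  term_map <- function(tag) {
    sel <- v$set_tag == tag
    m <- c(stats::setNames(v$vid[sel], v$t1[sel]),
           stats::setNames(v$vid[sel][!is.na(v$t2[sel])],
                           v$t2[sel][!is.na(v$t2[sel])]))
    m[!is.na(names(m)) & names(m) != "NA"]
  }
  mo <- term_map("O"); mr <- term_map("R")
  shared <- intersect(names(mo), names(mr))
  shared <- shared[order(suppressWarnings(as.integer(sub("[th]$", "", shared))),
                         shared)]
  edges <- data.frame(v_o = unname(mo[shared]), v_r = unname(mr[shared]),
                      terminal = shared, stringsAsFactors = FALSE)
  structure(list(vertices = v, edges = edges,
                 o_chains = o_chains, r_chains = r_chains),
            class = "adjacent_graph")
}

vertex_label <- function(v, vid) {
  t1 <- v$t1[vid]; t2 <- v$t2[vid]
  if (is.na(t2)) t1 else paste0(t1, t2)
}

#' Extract the maximal paths and cycles of an adjacent graph
#'
#' The edge set decomposes uniquely into open paths and cycles. Each record
#' is classified: `good` (even length, ends in the same set but different
#' adjacencies), `poor1_single` (one edge joining the same terminal of both
#' sets, or an isolated single terminal), `poor1_nonsingle` (other odd
#' paths), `poor2` (even, ends in the same adjacency), `circle` (closed).
#'
#' @param graph an `adjacent_graph`.
#' @return list of path records: vids, labels, length (edge count),
#'   end_terminals, end_chains, set of the ends, ptype.
#' @export
extract_paths <- function(graph) {
  v <- graph$vertices; e <- graph$edges
  n_v <- nrow(v)
  # incident edges per vertex
  inc <- vector("list", n_v)
  for (i in seq_len(nrow(e))) {
    inc[[e$v_o[i]]] <- c(inc[[e$v_o[i]]], i)
    inc[[e$v_r[i]]] <- c(inc[[e$v_r[i]]], i)
  }
  n_term <- ifelse(is.na(v$t2), 1L, 2L)
  deg <- lengths(inc)
  used_edge <- rep(FALSE, nrow(e))
  visited <- rep(FALSE, n_v)
  paths <- list()

  walk <- function(start) {
    vids <- start
    visited[start] <<- TRUE
    cur <- start
    closed <- FALSE
    repeat {
      nxt_e <- setdiff(inc[[cur]], which(used_edge))
      if (!length(nxt_e)) break
      ei <- nxt_e[1L]
      used_edge[ei] <<- TRUE
      nxt <- if (e$v_o[ei] == cur) e$v_r[ei] else e$v_o[ei]
      if (nxt == start && length(vids) > 1L) { closed <- TRUE; break }
      vids <- c(vids, nxt)
      visited[nxt] <<- TRUE
      cur <- nxt
    }
    list(vids = vids, closed = closed)
  }

  # path ends: single-terminal vertices (entering consumes their only
  # terminal) and conjunctions with an unmatched terminal. Open paths are
  # walked first, from the end vertex with the smallest terminal label.
  end_v <- which(n_term == 1L | deg < n_term)
  ord_key <- vapply(end_v, function(i) vertex_label(v, i), character(1))
  for (s in end_v[order(ord_key)]) {
    if (visited[s]) next
    w <- walk(s)
    paths[[length(paths) + 1L]] <- w
  }
  # remaining components are cycles (every vertex saturated)
  rest <- which(!visited & deg > 0L)
  rest_key <- vapply(rest, function(i) vertex_label(v, i), character(1))
  for (s in rest[order(rest_key)]) {
    if (visited[s]) next
    w <- walk(s)
    w$closed <- TRUE
    paths[[length(paths) + 1L]] <- w
  }
  # isolated vertices
  iso <- which(!visited & deg == 0L)
  for (s in iso) {
    paths[[length(paths) + 1L]] <- list(vids = s, closed = FALSE)
  }

  lapply(paths, function(p) {
    vids <- p$vids
    len <- if (p$closed) length(vids) else length(vids) - 1L
    a <- vids[1L]; b <- vids[length(vids)]
    same_set <- v$set_tag[a] == v$set_tag[b]
    same_chain <- same_set && v$set_tag[a] == v$set_tag[b] &&
      v$chain_idx[a] == v$chain_idx[b]
    labels <- vapply(vids, function(i) vertex_label(v, i), character(1))
    ptype <- if (p$closed) {
      "circle"
    } else if (len == 0L) {
      if (is.na(v$t2[a])) "poor1_single" else "poor2"
    } else if (len %% 2L == 1L) {
      if (len == 1L && is.na(v$t2[a]) && is.na(v$t2[b]) &&
          v$t1[a] == v$t1[b]) "poor1_single" else "poor1_nonsingle"
    } else {
      if (same_chain) "poor2" else "good"
    }
    list(vids = vids, labels = labels, length = len, closed = p$closed,
         ends_same_set = same_set, ends_same_adjacency = same_chain,
         end_terminals = c(v$t1[a], v$t1[b]),
         end_set = if (same_set) v$set_tag[a] else NA_character_,
         end_chains = c(v$chain_idx[a], v$chain_idx[b]),
         end_sets = c(v$set_tag[a], v$set_tag[b]),
         ptype = ptype)
  })
}

#' Algebraic rearrangement distance of an adjacent graph
#'
#' d = N - C - P/2 with C the number of cycles and P the number of open
#' paths. N is reported two ways: `n_contigs` (total chains over both sets,
#' the paper-literal reading, used for `d`) and `n_blocks` (the block count
#' of the underlying algebraic theory, used for `d_blocks`).
#'
#' @param graph an `adjacent_graph`.
#' @param paths optionally, precomputed [extract_paths()] output.
#' @return list with n_contigs, n_blocks, c, p, d, d_blocks.
#' @export
algebraic_distance <- function(graph, paths = NULL) {
  if (is.null(paths)) paths <- extract_paths(graph)
  cl <- vapply(paths, `[[`, logical(1), "closed")
  cyc <- sum(cl)
  open <- sum(!cl)
  n_contigs <- length(graph$o_chains) + length(graph$r_chains)
  n_blocks <- length(unique(abs(c(
    unlist(lapply(graph$o_chains, `[[`, "blocks")),
    unlist(lapply(graph$r_chains, `[[`, "blocks"))))))
  list(n_contigs = n_contigs, n_blocks = n_blocks, c = cyc, p = open,
       d = n_contigs - cyc - open / 2,
       d_blocks = n_blocks - cyc - open / 2)
}

# chain end whose terminal equals t: "L" (left end), "R" (right end), or NA
chain_end_side <- function(chain, t) {
  b <- chain$blocks
  if (terminal_entry(b[1L]) == t) return("L")
  if (terminal_exit(b[length(b)]) == t) return("R")
  NA_character_
}

# concatenate two chains so that `ta` (right end of A) meets `tb` (left end
# of B); callers orient the chains first
concat_chains <- function(a, b) {
  ka <- length(a$blocks)
  new_chain(id = paste0(a$id, "+", b$id), set_tag = a$set_tag,
            blocks = c(a$blocks, b$blocks),
            starts = c(a$starts, b$starts), ends = c(a$ends, b$ends),
            errs = c(a$errs, b$errs + ka))
}

#' Close good paths into cycles, fusing chains
#'
#' Each good path's two end terminals lie at the ends of two different
#' chains of the same set; closing the path joins those chains into one,
#' with orientation flips as required. Paths are applied in the
#' deterministic order produced by [extract_paths()]; a path whose end is no
#' longer a free chain end (consumed by an earlier fusion) is skipped and
#' logged.
#'
#' @param chains the chain list of the set being fused.
#' @param good_paths good path records whose `end_set` matches these chains.
#' @return list with `chains` (updated), `fused` (number applied),
#'   `skipped` (number skipped).
#' @export
fuse_good_paths <- function(chains, good_paths) {
  fused <- 0L; skipped <- 0L
  for (gp in good_paths) {
    ta <- gp$end_terminals[1L]; tb <- gp$end_terminals[2L]
    # locate the chains currently ending at ta and tb
    find_end <- function(t) {
      for (ci in seq_along(chains)) {
        side <- chain_end_side(chains[[ci]], t)
        if (!is.na(side)) return(list(ci = ci, side = side))
      }
      NULL
    }
    ea <- find_end(ta); eb <- find_end(tb)
    if (is.null(ea) || is.null(eb) || ea$ci == eb$ci) { skipped <- skipped + 1L; next }
    a <- chains[[ea$ci]]; b <- chains[[eb$ci]]
    if (ea$side == "L") a <- revneg_chain(a)   # ta to the right end of A
    if (eb$side == "R") b <- revneg_chain(b)   # tb to the left end of B
    merged <- concat_chains(a, b)
    chains[[ea$ci]] <- merged
    chains[[eb$ci]] <- NULL
    fused <- fused + 1L
  }
  list(chains = chains, fused = fused, skipped = skipped)
}

#' The path-type taxonomy of the adjacent graph
#'
#' Enumerates the feature combinations (path parity, whether the two ends lie
#' in the same set, whether they lie in the same adjacency), plus the closed
#' circle as the exceptional ninth row, and assigns each row its type. Rows
#' marked `absent` cannot occur: an odd path always ends in different sets
#' (and ends in different sets are never in the same adjacency); an even open
#' path always ends in the same set.
#'
#' @return data.frame with nine rows: no, length, same_set, same_adjacency,
#'   type.
#' @export
path_taxonomy <- function() {
  rows <- expand.grid(same_adjacency = c("Y", "N"), same_set = c("Y", "N"),
                      length = c("Odd", "Even"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("length", "same_set", "same_adjacency")]
  type <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    odd <- rows$length[i] == "Odd"
    ss <- rows$same_set[i] == "Y"
    sa <- rows$same_adjacency[i] == "Y"
    type[i] <- if (odd) {
      if (ss) "absent" else if (sa) "absent" else "poor1"
    } else {
      if (ss) { if (sa) "poor2" else "good" } else "absent"
    }
  }
  out <- cbind(no = seq_len(nrow(rows)), rows, type, stringsAsFactors = FALSE)
  rbind(out, data.frame(no = 9L, length = "Even", same_set = "N",
                        same_adjacency = "N", type = "circle",
                        stringsAsFactors = FALSE))
}
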