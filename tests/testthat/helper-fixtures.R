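# Shared test fixtures: hand-built alignment records, an independent
# igraph-based oracle for path/cycle counting, and simulator shortcuts.

# one alignment record row; spans derived from the CIGAR
make_rec <- function(read_id, contig_id, start, mate = 1L, cigar = "10M",
                     mapq = 60L, mean_bq = 38, is_reverse = FALSE,
                     mate_contig_id = NA_character_) {
  sp <- asmrec:::cigar_spans(cigar)
  data.frame(read_id = read_id, mate = mate, contig_id = contig_id,
             start = start, cigar = cigar, mapq = mapq,
             ref_span = sp$ref_span, query_len = sp$query_len,
             mean_bq = mean_bq, is_reverse = is_reverse,
             mate_contig_id = mate_contig_id, stringsAsFactors = FALSE)
}

bind_recs <- function(...) do.call(rbind, list(...))

empty_recs <- function() make_rec("x", "c", 0)[0, , drop = FALSE]

# a proper pair on one contig with the given outer distance
make_pair <- function(read_id, contig_id, start, outer, read_len = 10L,
                      mapq = 60L, mean_bq = 38) {
  rbind(
    make_rec(read_id, contig_id, start, mate = 1L,
             cigar = paste0(read_len, "M"), mapq = mapq, mean_bq = mean_bq,
             is_reverse = FALSE, mate_contig_id = contig_id),
    make_rec(read_id, contig_id, start + outer - read_len, mate = 2L,
             cigar = paste0(read_len, "M"), mapq = mapq, mean_bq = mean_bq,
             is_reverse = TRUE, mate_contig_id = contig_id))
}

# independent oracle: enumerate vertices/edges of the adjacent graph from
# first principles and count components with igraph; a component is a cycle
# iff its edge count equals its vertex count
oracle_graph_counts <- function(o_chains, r_chains) {
  verts <- character(0); vset <- character(0)
  edges_from <- list(O = list(), R = list())  # terminal -> vertex name
  for (side in list(list(tag = "O", chains = o_chains),
                    list(tag = "R", chains = r_chains))) {
    for (ch in side$chains) {
      b <- ch$blocks
      ends <- function(x) {
        c(ent = paste0(abs(x), if (x > 0) "t" else "h"),
          ext = paste0(abs(x), if (x > 0) "h" else "t"))
      }
      vnames <- character(0)
      term_sets <- list()
      k <- length(b)
      vnames <- c(vnames, paste0(side$tag, "_", ch$id, "_v0"))
      term_sets[[1]] <- ends(b[1])[["ent"]]
      if (k > 1) for (i in seq_len(k - 1)) {
        vnames <- c(vnames, paste0(side$tag, "_", ch$id, "_v", i))
        term_sets[[i + 1]] <- c(ends(b[i])[["ext"]], ends(b[i + 1])[["ent"]])
      }
      vnames <- c(vnames, paste0(side$tag, "_", ch$id, "_v", k))
      term_sets[[k + 1]] <- ends(b[k])[["ext"]]
      for (i in seq_along(vnames)) {
        verts <- c(verts, vnames[i])
        for (t in term_sets[[i]]) {
          edges_from[[side$tag]][[t]] <- vnames[i]
        }
      }
    }
  }
  shared <- intersect(names(edges_from$O), names(edges_from$R))
  el <- cbind(unlist(edges_from$O[shared]), unlist(edges_from$R[shared]))
  g <- igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  memb <- comp$membership
  e_ends <- igraph::ends(g, igraph::E(g))
  e_comp <- memb[e_ends[, 1]]
  n_edges <- tabulate(e_comp, nbins = comp$no)
  n_verts <- tabulate(memb, nbins = comp$no)
  cycles <- sum(n_edges == n_verts & n_verts >= 2)
  paths <- comp$no - cycles
  list(c = cycles, p = paths,
       n_contigs = length(o_chains) + length(r_chains))
}

# quick simulator scenario: genome + two assemblies with complementary
# clean breaks
complementary_fixture <- function(seed, G = 100000L, n_breaks = 3L) {
  gen <- simulate_genome(G, gc = 0.5, seed = seed)
  set.seed(seed + 1L)
  brA <- sort(sample(seq(5000L, G - 5000L), n_breaks))
  brB <- sort(sample(setdiff(seq(5000L, G - 5000L), outer(brA, -2000:2000, "+")),
                     n_breaks))
  plans <- list(A = assembly_plan_from_breaks(G, brA),
                B = assembly_plan_from_breaks(G, brB))
  sa <- simulate_assemblies(gen, plans)
  list(genome = gen, sets = sa$sets, truth = sa$truth,
       breaks = list(A = brA, B = brB))
}

# is every contig of a set an exact substring of the genome (either strand)?
all_substrings_of <- function(set, genome) {
  rc <- asmrec:::revcomp(genome)
  all(vapply(set$contigs, function(s) {
    grepl(s, genome, fixed = TRUE) || grepl(s, rc, fixed = TRUE)
  }, logical(1)))
}
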