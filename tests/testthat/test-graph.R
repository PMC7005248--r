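fig2 <- function() figure2_fixture()

path_by_type <- function(paths, type) {
  paths[vapply(paths, `[[`, character(1), "ptype") == type]
}

path_strings <- function(paths) {
  vapply(paths, function(p) paste(p$labels, collapse = ","), character(1))
}

test_that("the worked-example graph has the printed edges and vertices", {
  fx <- fig2()
  g <- build_graph(fx$o_chains, fx$r_chains)
  labs_o <- apply(g$vertices[g$vertices$set_tag == "O", c("t1", "t2")], 1,
                  function(x) paste(na.omit(x), collapse = ""))
  expect_true(all(c("1t", "1h5t", "5h", "9t", "9h", "3h", "3t7t", "6h4t")
                  %in% labs_o))
  # the edge between 1h5t and 1h6t (shared terminal 1h)
  pair <- paste(
    asmrec:::vertex_label(g$vertices, g$edges$v_o[g$edges$terminal == "1h"]),
    asmrec:::vertex_label(g$vertices, g$edges$v_r[g$edges$terminal == "1h"]))
  expect_equal(pair, "1h5t 1h6t")
  # edges join opposite sets only, and every vertex has degree <= 2
  expect_true(all(g$vertices$set_tag[g$edges$v_o] == "O"))
  expect_true(all(g$vertices$set_tag[g$edges$v_r] == "R"))
  deg <- tabulate(c(g$edges$v_o, g$edges$v_r), nbins = nrow(g$vertices))
  expect_true(all(deg <= 2))

  # duplicated block in one set is rejected
  bad <- c(fx$o_chains, fx$o_chains[1])
  expect_error(build_graph(bad, fx$r_chains), "twice")
})

test_that("identical chain sets are at distance 0", {
  ch <- list(asmrec:::new_chain("c1", "O", c(1L, 2L)))
  ch_r <- list(asmrec:::new_chain("c1", "R", c(1L, 2L)))
  g <- build_graph(ch, ch_r)
  paths <- extract_paths(g)
  types <- vapply(paths, `[[`, character(1), "ptype")
  # the shared interior conjunction forms a 2-cycle; the chain-end terminals
  # pair off as trivial single paths
  expect_equal(sum(types == "circle"), 1L)
  expect_setequal(types[types != "circle"], "poor1_single")
  d <- algebraic_distance(g, paths)
  expect_equal(d$c, 1L)
  expect_equal(d$p, 2L)
  expect_equal(d$d_blocks, 2 - 1 - 2 / 2)  # = 0: nothing to rearrange
})

test_that("worked-example paths match the printed classification", {
  fx <- fig2()
  g <- build_graph(fx$o_chains, fx$r_chains)
  paths <- extract_paths(g)
  good <- path_strings(path_by_type(paths, "good"))
  expect_setequal(good, c("2h,2h7t,3t7t,4h3t,4h", "3h,3h9t,9t", "7h,7h8t,8t"))
  nonsingle <- path_strings(path_by_type(paths, "poor1_nonsingle"))
  expect_equal(nonsingle, "4t,6h4t,6h5t,1h5t,1h6t,6t")
  singles <- path_strings(path_by_type(paths, "poor1_single"))
  expect_setequal(singles, c("1t,1t", "5h,5h", "9h,9h"))
  poor2 <- path_strings(path_by_type(paths, "poor2"))
  expect_equal(poor2, "2t,8h2t,8h")
  # every edge lies in exactly one path
  used <- sum(vapply(paths, function(p) {
    if (p$closed) p$length else p$length
  }, integer(1)))
  expect_equal(used, nrow(g$edges))
})

test_that("an unmatched single block yields isolated single-terminal paths", {
  o <- list(asmrec:::new_chain("c1", "O", 1L),
            asmrec:::new_chain("c2", "O", 2L))
  r <- list(asmrec:::new_chain("c1", "R", 1L))
  g <- build_graph(o, r)
  paths <- extract_paths(g)
  iso <- path_by_type(paths, "poor1_single")
  expect_true(any(vapply(iso, function(p) identical(p$labels, c("2t")), logical(1))))
  d <- algebraic_distance(g, paths)
  expect_equal(d$c, 0L)
})

test_that("fusions reproduce the printed joins", {
  fx <- fig2()
  g <- build_graph(fx$o_chains, fx$r_chains)
  paths <- extract_paths(g)
  good <- path_by_type(paths, "good")
  # apply the [4h,2h] fusion alone: [8,2] + [6,4] -> [8,2,-4,-6]
  g42 <- good[vapply(good, function(p) setequal(p$end_terminals, c("4h", "2h")),
                     logical(1))]
  res <- fuse_good_paths(fx$o_chains, g42)
  joined <- res$chains[[which(vapply(res$chains, function(ch)
    length(ch$blocks) == 4L, logical(1)))]]
  expect_true(chain_equivalent(joined$blocks, c(8L, 2L, -4L, -6L)))

  # the [9t,3h] fusion: [9] + [-3,7] -> [-9,-3,7]
  g93 <- good[vapply(good, function(p) setequal(p$end_terminals, c("9t", "3h")),
                     logical(1))]
  res2 <- fuse_good_paths(fx$o_chains, g93)
  joined2 <- res2$chains[[which(vapply(res2$chains, function(ch)
    length(ch$blocks) == 3L, logical(1)))]]
  expect_true(chain_equivalent(joined2$blocks, c(-9L, -3L, 7L)))

  # all three fusions transitively: [-9,-3,7,8,2,-4,-6]
  res3 <- fuse_good_paths(fx$o_chains, good)
  big <- res3$chains[[which.max(vapply(res3$chains, function(ch)
    length(ch$blocks), integer(1)))]]
  expect_true(chain_equivalent(big$blocks, c(-9L, -3L, 7L, 8L, 2L, -4L, -6L)))
  expect_equal(res3$fused, 3L)
  # each fusion reduces the chain count by one and loses no block
  expect_equal(length(res3$chains), length(fx$o_chains) - 3L)
  expect_setequal(abs(unlist(lapply(res3$chains, `[[`, "blocks"))), 1:9)
})

test_that("fusion direction is reversal-invariant", {
  o <- list(asmrec:::new_chain("a", "O", c(1L, 2L)),
            asmrec:::new_chain("b", "O", c(3L, 4L)))
  gp <- list(list(end_terminals = c("2h", "3t"), end_set = "O"))
  gp_rev <- list(list(end_terminals = c("3t", "2h"), end_set = "O"))
  f1 <- fuse_good_paths(o, gp)$chains[[1]]$blocks
  f2 <- fuse_good_paths(o, gp_rev)$chains[[1]]$blocks
  expect_true(chain_equivalent(f1, f2))
  expect_true(chain_equivalent(f1, c(1L, 2L, 3L, 4L)))
})

test_that("distance equals the independent component-counting oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:40) {
    n_blocks <- 2L + (seed %% 7L)
    inst <- random_chain_instance(n_blocks, seed = seed)
    g <- build_graph(inst$o_chains, inst$r_chains)
    got <- algebraic_distance(g)
    oracle <- oracle_graph_counts(inst$o_chains, inst$r_chains)
    expect_equal(got$c, oracle$c, info = paste("seed", seed))
    expect_equal(got$p, oracle$p, info = paste("seed", seed))
    expect_equal(got$d, oracle$n_contigs - oracle$c - oracle$p / 2,
                 info = paste("seed", seed))
  }
})

test_that("the path taxonomy matches the printed table", {
  tx <- path_taxonomy()
  expect_equal(nrow(tx), 9L)
  # exactly as printed: rows 4/5/6 are poor-1/poor-2/good, row 9 the circle,
  # the remaining five feature combinations are infeasible
  expect_equal(tx$type,
               c("absent", "absent", "absent", "poor1", "poor2", "good",
                 "absent", "absent", "circle"))
  expect_equal(tx$length, c(rep("Odd", 4), rep("Even", 5)))
  expect_equal(tx$same_set, c("Y", "Y", "N", "N", "Y", "Y", "N", "N", "N"))
  expect_equal(tx$same_adjacency, c("Y", "N", "Y", "N", "Y", "N", "Y", "N", "N"))
})
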