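test_that("edge construction keeps only DE miRNAs and signs edges by direction", {
  pairs <- data.frame(mirna_id = c("hsa-miR-UP", "hsa-mir-down", "hsa-mir-other"),
                      gene_symbol = c("G1", "G1", "G2"), stringsAsFactors = FALSE)
  de <- data.frame(feature_id = c("hsa-mir-up", "hsa-mir-down"),
                   direction = c("up", "down"), stringsAsFactors = FALSE)
  net <- build_signed_network(pairs, de)
  expect_equal(nrow(net$edges), 2L)                    # non-DE pair excluded
  expect_equal(net$n_dropped_pairs, 1L)
  expect_equal(sort(net$edges$weight), c(-1L, 1L))
  expect_equal(net$edges$weight[net$edges$mirna_id == "hsa-mir-up"], 1L)

  one <- build_signed_network(pairs[1, ], de[1, ])
  expect_equal(one$edges$weight, 1L)

  bad <- de
  bad$direction[1] <- NA
  expect_error(build_signed_network(pairs, bad), "direction")
})

test_that("node strengths follow the repression sign convention", {
  # 2 up + 1 down -> strength +1, predicted down
  pairs <- data.frame(
    mirna_id = c("m1", "m2", "m3"), gene_symbol = "G", stringsAsFactors = FALSE)
  de <- data.frame(feature_id = c("m1", "m2", "m3"),
                   direction = c("up", "up", "down"), stringsAsFactors = FALSE)
  s <- node_strength(build_signed_network(pairs, de))
  expect_equal(s$node_strength, 1L)
  expect_equal(s$predicted_direction, "down")

  # 4 up, 0 down -> +4, predicted down (CADM2-style row)
  pairs4 <- data.frame(mirna_id = paste0("m", 1:4), gene_symbol = "CADM2",
                       stringsAsFactors = FALSE)
  de4 <- data.frame(feature_id = paste0("m", 1:4), direction = "up",
                    stringsAsFactors = FALSE)
  s4 <- node_strength(build_signed_network(pairs4, de4))
  expect_equal(s4$node_strength, 4L)
  expect_equal(s4$predicted_direction, "down")

  # 8 more down than up -> -8, predicted up (KLHL15-style row)
  pairs8 <- data.frame(mirna_id = paste0("m", 1:8), gene_symbol = "KLHL15",
                       stringsAsFactors = FALSE)
  de8 <- data.frame(feature_id = paste0("m", 1:8), direction = "down",
                    stringsAsFactors = FALSE)
  s8 <- node_strength(build_signed_network(pairs8, de8))
  expect_equal(s8$node_strength, -8L)
  expect_equal(s8$predicted_direction, "up")
})

test_that("strength invariants hold on random networks", {
  for (seed in 1:8) {
    rn <- random_network(seed = seed)
    net <- build_signed_network(rn$pairs, rn$de)
    s <- node_strength(net)
    # parity and degree bounds
    expect_true(all(abs(s$node_strength) <= s$degree))
    expect_true(all((s$node_strength - s$degree) %% 2 == 0))
    # total strength identity
    expect_equal(sum(s$node_strength),
                 sum(net$edges$weight > 0) - sum(net$edges$weight < 0))
    # brute-force recount from the raw edge list
    brute <- vapply(s$gene_symbol, function(g) {
      e <- net$edges[net$edges$gene_symbol == g, ]
      sum(e$weight)
    }, 0L)
    expect_equal(s$node_strength, unname(brute))
  }
})

test_that("flipping directions negates strengths and is an involution", {
  rn <- random_network(seed = 99)
  net <- build_signed_network(rn$pairs, rn$de)
  flipped <- flip_directions(net)
  s <- node_strength(net)
  sf <- node_strength(flipped)
  expect_equal(sf$node_strength, -s$node_strength)
  swap <- c(up = "down", down = "up", none = "none")
  expect_equal(sf$predicted_direction, unname(swap[s$predicted_direction]))
  back <- flip_directions(flipped)
  expect_equal(node_strength(back), s)
  expect_equal(back$mirna_direction, net$mirna_direction)
})

test_that("top targets sort by |strength| with alphabetical ties and support the emphasis cutoff", {
  pred <- data.frame(gene_symbol = c("B", "A", "C", "D"),
                     degree = c(7, 8, 2, 4),
                     n_up_edges = c(7, 0, 2, 4), n_down_edges = c(0, 8, 0, 0),
                     node_strength = c(7L, -8L, 2L, 4L),
                     predicted_direction = c("down", "up", "down", "down"),
                     stringsAsFactors = FALSE)
  out <- top_targets(pred)
  expect_equal(out$node_strength, c(-8L, 7L, 4L, 2L))

  tie <- pred
  tie$node_strength <- c(4L, -4L, 4L, 1L)
  expect_equal(top_targets(tie)$gene_symbol, c("A", "B", "C", "D"))

  filt <- top_targets(pred, min_abs_strength = 2)
  expect_true(all(abs(filt$node_strength) >= 2))
  strong <- rbind(pred, data.frame(gene_symbol = "E", degree = 1, n_up_edges = 1,
                                   n_down_edges = 0, node_strength = 1L,
                                   predicted_direction = "down"))
  expect_false("E" %in% top_targets(strong, min_abs_strength = 2)$gene_symbol)
})

test_that("computed strengths recover the planted truth exactly", {
  cfg <- small_sim_config(seed = 77, n_planted = 20)
  sim <- simulate_counts(cfg)
  db <- simulate_interaction_db(cfg, sim$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(db, path)
  pairs <- read_interactions(path)
  truth_de <- data.frame(
    feature_id = names(sim$truth$true_de_mirnas),
    direction = ifelse(sim$truth$true_de_mirnas > 0, "up", "down"),
    stringsAsFactors = FALSE)
  net <- build_signed_network(pairs, truth_de)
  # edge set equals the planted edges
  key <- function(m, g) sort(paste(m, g))
  expect_identical(key(net$edges$mirna_id, net$edges$gene_symbol),
                   key(sim$truth$true_edges$mirna_id, sim$truth$true_edges$gene_symbol))
  s <- node_strength(net)
  truth_s <- sim$truth$true_node_strengths[s$gene_symbol]
  expect_identical(s$node_strength, unname(truth_s))
})
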