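mine_toy <- function(labels, strands = NULL, families = NULL, ...) {
  genes <- toy_genes(labels, strands)
  ann <- toy_annotations(genes, labels, families)
  mine_assembly(genes, ann, ...)
}

test_that("SusC/D pairing follows the greedy closest-pair rule", {
  genes <- toy_genes(c("NONE", "SUSC", "SUSD", "NONE"))
  ann <- toy_annotations(genes, c("NONE", "SUSC", "SUSD", "NONE"))
  p <- find_suscd_pairs(genes, ann)
  expect_identical(nrow(p), 1L)
  expect_identical(p$susc_id, genes$gene_id[2])
  expect_identical(p$susd_id, genes$gene_id[3])

  # too far apart at max_gap = 1
  lab <- c("SUSC", "NONE", "NONE", "NONE", "SUSD")
  genes <- toy_genes(lab); ann <- toy_annotations(genes, lab)
  expect_identical(nrow(find_suscd_pairs(genes, ann)), 0L)
  expect_identical(nrow(find_suscd_pairs(genes, ann, max_gap = 3)), 1L)

  # either gene order forms a pair
  lab <- c("SUSD", "SUSC")
  genes <- toy_genes(lab); ann <- toy_annotations(genes, lab)
  expect_identical(nrow(find_suscd_pairs(genes, ann)), 1L)

  # a run of susC,susD,susC,susD yields two disjoint pairs
  lab <- c("SUSC", "SUSD", "SUSC", "SUSD")
  genes <- toy_genes(lab); ann <- toy_annotations(genes, lab)
  p <- find_suscd_pairs(genes, ann)
  expect_identical(nrow(p), 2L)
  expect_identical(p$lo_index, c(0L, 2L))

  # strand rule
  lab <- c("SUSC", "SUSD")
  genes <- toy_genes(lab, strands = c("+", "-"))
  ann <- toy_annotations(genes, lab)
  expect_identical(nrow(find_suscd_pairs(genes, ann)), 0L)
  expect_identical(nrow(find_suscd_pairs(genes, ann,
                                         require_same_strand = FALSE)), 1L)
})

test_that("pairing matches the independent oracle on all arrangements up to length 6", {
  alphabet <- c("NONE", "SUSC", "SUSD")
  for (n in 2:6) {
    grid <- enum_flanks(n, 0:2) + 1L
    for (r in seq_len(nrow(grid))) {
      lab <- alphabet[grid[r, ]]
      if (sum(lab == "SUSC") == 0 || sum(lab == "SUSD") == 0) next
      genes <- toy_genes(lab)
      ann <- toy_annotations(genes, lab)
      got <- find_suscd_pairs(genes, ann)
      want <- oracle_pairs(lab)
      expect_identical(nrow(got), length(want))
      if (length(want)) {
        want_lo <- vapply(want, function(p) p[1] - 1L, integer(1))
        expect_identical(sort(got$lo_index), sort(want_lo))
      }
    }
  }
})

test_that("span extension honours the seven-gene frame and GT exclusion", {
  # CAZyme three genes upstream of the anchor extends the span to it
  lab <- c("NONE", "CAZ", "NONE", "NONE", "SUSC", "SUSD")
  expect_identical(unname(pul_extend_labels(lab, 5, 6)), c(2L, 6L))

  # nearest CAZyme 8 genes away is outside a 7-gene frame
  lab <- c("SUSC", "SUSD", rep("NONE", 7), "CAZ")
  expect_identical(unname(pul_extend_labels(lab, 1, 2)), c(1L, 2L))
  # ... but inside an 8-gene frame
  expect_identical(unname(pul_extend_labels(lab, 1, 2, frame = 8)), c(1L, 10L))

  # glycosyl transferases never extend the span
  lab <- c("SUSC", "SUSD", "NONE", "GT")
  expect_identical(unname(pul_extend_labels(lab, 1, 2)), c(1L, 2L))

  # each absorbed CAZyme re-opens the window (iterative semantics) ...
  lab <- c("SUSC", "SUSD", rep("NONE", 6), "CAZ", rep("NONE", 6), "CAZ")
  expect_identical(unname(pul_extend_labels(lab, 1, 2)), c(1L, 16L))
  # ... while fixed-window semantics stop after the first window
  expect_identical(unname(pul_extend_labels(lab, 1, 2, window = "fixed")),
                   c(1L, 9L))
})

test_that("increasing the frame never shrinks a span", {
  set.seed(42)
  for (r in 1:200) {
    n <- sample(5:15, 1)
    lab <- sample(c("NONE", "CAZ", "GT"), n, replace = TRUE)
    a <- sample(seq_len(n - 1), 1)
    lab[a] <- "SUSC"; lab[a + 1] <- "SUSD"
    prev <- NULL
    for (frame in 1:9) {
      span <- pul_extend_labels(lab, a, a + 1, frame = frame)
      if (!is.null(prev)) {
        expect_lte(span[1], prev[1])
        expect_gte(span[2], prev[2])
      }
      prev <- span
    }
  }
})

test_that("extraction equals the fixed-point oracle on random arrangements", {
  set.seed(7)
  for (r in 1:500) {
    n <- sample(4:15, 1)
    lab <- sample(c("NONE", "CAZ", "GT"), n, replace = TRUE)
    a <- sample(seq_len(n - 1), 1)
    lab[a] <- "SUSC"; lab[a + 1] <- "SUSD"
    genes <- toy_genes(lab)
    ann <- toy_annotations(genes, lab)
    anchor <- find_suscd_pairs(genes, ann)
    pul <- extract_pul(anchor[1, ], genes, ann)
    want <- oracle_extend(lab, a, a + 1)
    expect_identical(unname(pul$span),
                     c(want[1] - 1L, want[2] - 1L))  # spans are 0-based
  }
})

test_that("screen filter requires a GH26 (any subfamily)", {
  kept <- screen_filter(list(toy_pul(c("GH26", "GH27"))))
  expect_length(kept, 1L)
  expect_length(screen_filter(list(toy_pul(c("GH5", "GH27")))), 0L)
  expect_length(screen_filter(list(toy_pul(character(0)))), 0L)
  expect_length(screen_filter(list(toy_pul(c("GH26_1", "GH5")))), 1L)
  # GH260-style families must not match
  expect_length(screen_filter(list(toy_pul("GH260"))), 0L)
  summary <- attr(screen_filter(list(toy_pul("GH26"), toy_pul("GH5"))),
                  "screen_summary")
  expect_identical(summary$kept, 1L)
  expect_identical(summary$dropped, 1L)
})

test_that("mining recovers planted PULs exactly at zero noise", {
  for (s in 1:10) {
    g <- generate_genome(2, 60, n_puls = 2, n_decoys = 2, seed = s)
    h <- generate_hit_tables(g, noise_config(seed = s))
    ann <- annotate_genome(g$genes, h$domain_hits, h$search_hits)
    got <- as.data.frame(mine_assembly(g$genes, ann))
    want <- g$planted_puls
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$contig_id, want$contig_id)
    expect_identical(got$start_index, want$start_index)
    expect_identical(got$end_index, want$end_index)
  }

  # decoys alone yield nothing
  g <- generate_genome(1, 60, n_puls = 0, n_decoys = 3, seed = 13)
  h <- generate_hit_tables(g, noise_config(seed = 13))
  ann <- annotate_genome(g$genes, h$domain_hits, h$search_hits)
  expect_length(mine_assembly(g$genes, ann), 0L)
})

test_that("overlapping spans from distinct anchors merge into one PUL", {
  lab <- c("CAZ", "SUSC", "SUSD", "NONE", "CAZ", "NONE", "SUSC", "SUSD", "CAZ")
  genes <- toy_genes(lab)
  ann <- toy_annotations(genes, lab)
  puls <- mine_assembly(genes, ann)
  expect_length(puls, 1L)
  expect_true(puls[[1]]$merged)
  expect_identical(unname(puls[[1]]$span), c(0L, 8L))
  expect_length(puls[[1]]$anchors, 2L)
})

test_that("anchor-only clusters carry an empty family set and are screened out", {
  lab <- c("NONE", "SUSC", "SUSD", "NONE")
  genes <- toy_genes(lab)
  ann <- toy_annotations(genes, lab)
  all_puls <- mine_assembly(genes, ann, require_gh26 = FALSE)
  expect_length(all_puls, 1L)
  expect_length(all_puls[[1]]$family_set, 0L)
  expect_length(mine_assembly(genes, ann), 0L)
})
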