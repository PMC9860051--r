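test_that("generators are deterministic under a fixed seed", {
  g1 <- generate_genome(2, 50, n_puls = 2, n_decoys = 3, seed = 0)
  g2 <- generate_genome(2, 50, n_puls = 2, n_decoys = 3, seed = 0)
  expect_identical(g1, g2)

  h1 <- generate_hit_tables(g1, noise_config(fp_rate = 0.3, fn_rate = 0.1,
                                             near_threshold_fraction = 0.5,
                                             seed = 4))
  h2 <- generate_hit_tables(g1, noise_config(fp_rate = 0.3, fn_rate = 0.1,
                                             near_threshold_fraction = 0.5,
                                             seed = 4))
  expect_identical(h1, h2)

  p1 <- generate_proteome(100, effect_proteins = 1:5, effect_fold = 4,
                          missing_rate = 0.2, seed = 9)
  p2 <- generate_proteome(100, effect_proteins = 1:5, effect_fold = 4,
                          missing_rate = 0.2, seed = 9)
  expect_identical(p1, p2)

  a1 <- generate_arrays(3, 4, deletion_targets = data.frame(
    extract_id = "extract01", probe_id = "probe02", treatment = "GH26C"),
    deletion_depth = 0.5, noise_cv = 0.1, seed = 2)
  a2 <- generate_arrays(3, 4, deletion_targets = data.frame(
    extract_id = "extract01", probe_id = "probe02", treatment = "GH26C"),
    deletion_depth = 0.5, noise_cv = 0.1, seed = 2)
  expect_identical(a1, a2)

  # different seeds change the gene layout
  g3 <- generate_genome(2, 50, n_puls = 2, n_decoys = 3, seed = 99)
  expect_false(identical(g1$genes, g3$genes))
})

test_that("planted genomes satisfy their structural invariants", {
  g <- generate_genome(1, 60, n_puls = 1, n_decoys = 3, seed = 0)
  expect_identical(nrow(g$planted_puls), 1L)
  expect_setequal(names(g$true_labels), g$genes$gene_id)

  # exactly one SusC/D pair inside the planted PUL
  span <- g$planted_puls
  inside <- g$genes$contig_id == span$contig_id &
    g$genes$order_index >= span$start_index &
    g$genes$order_index <= span$end_index
  lab <- g$true_labels[g$genes$gene_id[inside]]
  expect_identical(sum(lab == "SUSC"), 1L)
  expect_identical(sum(lab == "SUSD"), 1L)

  # coordinates strictly increasing and non-overlapping within contigs
  for (ctg in unique(g$genes$contig_id)) {
    gg <- g$genes[g$genes$contig_id == ctg, ]
    gg <- gg[order(gg$order_index), ]
    expect_true(all(diff(gg$start) > 0))
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }

  # planted spans disjoint within a contig across many seeds
  for (s in 1:20) {
    gm <- generate_genome(2, 60, n_puls = 3, n_decoys = 2, seed = s)
    for (ctg in unique(gm$planted_puls$contig_id)) {
      p <- gm$planted_puls[gm$planted_puls$contig_id == ctg, ]
      p <- p[order(p$start_index), ]
      if (nrow(p) > 1) {
        expect_true(all(p$start_index[-1] > p$end_index[-nrow(p)]))
      }
    }
  }
})

test_that("over-full genomes raise a capacity error", {
  expect_error(generate_genome(1, 20, n_puls = 2, n_decoys = 0, seed = 1),
               "capacity")
  expect_error(generate_genome(1, 10, n_puls = 0, n_decoys = 5, seed = 1),
               "capacity")
})

test_that("zero-noise hit tables reproduce the planted labels exactly", {
  for (s in c(0, 7, 23)) {
    g <- generate_genome(2, 45, n_puls = 1, n_decoys = 3, seed = s)
    h <- generate_hit_tables(g, noise_config(seed = s))
    ann <- annotate_genome(g$genes, h$domain_hits, h$search_hits)
    got <- setNames(ann$family, ann$gene_id)
    want <- g$true_labels[g$true_labels != "NONE"]
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("generated hit fields satisfy their pass/fail intent", {
  g <- generate_genome(2, 60, n_puls = 2, n_decoys = 3, seed = 5)
  h <- generate_hit_tables(g, noise_config(fp_rate = 0.6, fn_rate = 0.2,
                                           near_threshold_fraction = 0.7,
                                           seed = 5))
  # every emitted domain hit is generated to pass the dbCAN-style filter
  kept <- filter_domain_hits(h$domain_hits)
  expect_identical(nrow(kept), nrow(h$domain_hits))

  # spurious hits never survive confirmation; true CAZy hits always do
  ann_c <- annotate_genome(g$genes, h$domain_hits, h$search_hits,
                           mode = "confirmed")
  ann_h <- annotate_genome(g$genes, h$domain_hits, h$search_hits,
                           mode = "hmm_only")
  fp <- h$intents$protein_id[h$intents$type == "fp"]
  expect_true(length(fp) > 5)                      # fp_rate actually applied
  expect_length(intersect(ann_c$gene_id, fp), 0L)
  expect_true(all(fp %in% ann_h$gene_id))          # but they pass HMM-only
  tr <- h$intents[h$intents$type == "true" &
                    !(h$intents$family %in% c("SUSC", "SUSD")) &
                    !grepl("^GT", h$intents$family), ]
  expect_true(all(tr$protein_id %in% ann_c$gene_id))
})

test_that("synthetic proteomes honour their contracts", {
  p <- generate_proteome(50, effect_proteins = 1:5, effect_fold = 1, seed = 1)
  expect_false(any(p$truth$is_effect))   # fold 1 means no true positives

  p2 <- generate_proteome(50, effect_proteins = 1:5, effect_fold = 8, seed = 1)
  expect_identical(sum(p2$truth$is_effect), 5L)
  # the fold change is applied in the first condition only
  first <- p2$metadata$condition == p2$metadata$condition[1]
  expect_equal(p2$intensities[1:5, first], 8 * p$intensities[1:5, first])
  expect_equal(p2$intensities[, !first], p$intensities[, !first])

  p3 <- generate_proteome(30, missing_rate = 1, seed = 2)
  expect_true(all(is.na(p3$intensities)))
  expect_length(detection_filter(p3$intensities, p3$metadata), 0L)

  expect_error(generate_proteome(10, n_reps = 1), "n_reps")
  expect_error(generate_proteome(10, effect_fold = 0), "effect_fold")
  expect_error(generate_proteome(10, missing_rate = 1.2), "missing_rate")
})

test_that("synthetic arrays plant deletions only where asked", {
  tgt <- data.frame(extract_id = "extract02", probe_id = "probe01",
                    treatment = "GH26C", stringsAsFactors = FALSE)
  a0 <- generate_arrays(3, 2, deletion_targets = tgt, deletion_depth = 0,
                        seed = 3)
  means <- mean_replicates(a0$spots)
  norm <- normalize_dataset(means)
  sc <- epitope_deletion_score(norm, "GH26C")
  expect_true(all(abs(sc$deletion_score) < 1e-12))

  a1 <- generate_arrays(3, 2, deletion_targets = tgt, deletion_depth = 1,
                        seed = 3)
  sc1 <- epitope_deletion_score(normalize_dataset(mean_replicates(a1$spots)),
                                "GH26C")
  hit <- sc1$extract_id == "extract02" & sc1$probe_id == "probe01"
  expect_equal(sc1$deletion_score[hit], 100)
  expect_true(all(sc1$deletion_score[!hit] == 0))

  expect_error(generate_arrays(2, 2, deletion_targets = data.frame(
    extract_id = "extract01", probe_id = "probe01", treatment = "buffer")),
    "control")
})
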