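dh <- function(protein = "p1", profile = "GH26", e = 1e-10, aln = 120,
               cov = 0.5, from = 1) {
  data.frame(protein_id = protein, profile_name = profile, e_value = e,
             alignment_length = aln, profile_coverage = cov,
             env_from = from, env_to = from + aln - 1,
             stringsAsFactors = FALSE)
}

sh <- function(query = "p1", family = "GH26", e = 1e-25, qcov = 50, pid = 40) {
  data.frame(query_id = query, subject_id = paste0("db|", family),
             subject_family = family, percent_identity = pid,
             query_coverage = qcov, e_value = e, stringsAsFactors = FALSE)
}

test_that("domain-hit thresholds follow the dbCAN parser rules", {
  expect_identical(nrow(filter_domain_hits(dh(e = 1e-6, aln = 120, cov = 0.5))), 1L)
  expect_identical(nrow(filter_domain_hits(dh(e = 1e-4, aln = 120, cov = 0.5))), 0L)
  # short alignments get the relaxed e-value rule
  expect_identical(nrow(filter_domain_hits(dh(e = 1e-4, aln = 60, cov = 0.5))), 1L)
  expect_identical(nrow(filter_domain_hits(dh(e = 1e-2, aln = 60, cov = 0.5))), 0L)
  # coverage bound is strict
  expect_identical(nrow(filter_domain_hits(dh(cov = 0.30))), 0L)
  expect_identical(nrow(filter_domain_hits(dh(cov = 0.31))), 1L)
  # constants are configurable
  rules <- annotation_rules(e_long = 1e-10)
  expect_identical(nrow(filter_domain_hits(dh(e = 1e-6), rules)), 0L)
  # malformed rows are reported with their row number
  bad <- rbind(dh(), dh(e = -1))
  expect_error(filter_domain_hits(bad), "row\\(s\\): 2")
})

test_that("overlapping hits on one protein resolve to the lower e-value", {
  # enumerate overlap fractions around the 50% rule on hit pairs
  for (shift in c(0, 12, 60, 108, 130)) {
    a <- dh(profile = "GH26", e = 1e-10, from = 1, aln = 120)
    b <- dh(profile = "GH5", e = 1e-8, from = 1 + shift, aln = 120)
    got <- filter_domain_hits(rbind(a, b))
    overlap <- max(0, 120 - shift) / 120
    if (overlap > 0.5) {
      expect_identical(got$profile_name, "GH26")  # lower e-value wins
    } else {
      expect_setequal(got$profile_name, c("GH26", "GH5"))
    }
  }
  # order of rows must not matter
  a <- dh(profile = "GH26", e = 1e-10)
  b <- dh(profile = "GH5", e = 1e-8, from = 10)
  expect_identical(filter_domain_hits(rbind(a, b))$profile_name,
                   filter_domain_hits(rbind(b, a))$profile_name)
})

test_that("filtering is idempotent on random tables", {
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    hits <- data.frame(
      protein_id = sample(sprintf("p%02d", 1:8), n, replace = TRUE),
      profile_name = sample(c("GH26", "GH5", "CE2", "GT2"), n, replace = TRUE),
      e_value = 10^runif(n, -30, -1),
      alignment_length = sample(40:300, n, replace = TRUE),
      profile_coverage = runif(n),
      env_from = sample(1:200, n, replace = TRUE),
      stringsAsFactors = FALSE)
    hits$env_to <- hits$env_from + hits$alignment_length - 1
    once <- filter_domain_hits(hits)
    expect_identical(filter_domain_hits(once), once)
  }
})

test_that("SusC/D classification maps the published profile set", {
  expect_identical(classify_sus(dh(profile = "TIGR04056"))$label, "SUSC")
  for (p in c("PF12741.10", "PF12771.10", "PF14322.9", "PF07980.14",
              "PF14322")) {
    expect_identical(classify_sus(dh(profile = p))$label, "SUSD")
  }
  expect_message(res <- classify_sus(dh(profile = "PF99999")), "unrecognized")
  expect_identical(nrow(res), 0L)
  # both profile classes on one protein: conflict, lower e-value wins
  both <- rbind(dh(profile = "TIGR04056", e = 1e-30),
                dh(profile = "PF12741.10", e = 1e-10, from = 300))
  res <- classify_sus(both)
  expect_identical(res$label, "SUSC")
  expect_true(res$conflict)
})

test_that("confirmation thresholds are inclusive at the boundary", {
  calls <- data.frame(protein_id = "p1", label = "GH26", family = "GH26",
                      evidence = "HMM", e_value = 1e-10, conflict = FALSE,
                      stringsAsFactors = FALSE)
  keep <- function(hit) nrow(confirm_calls(calls, hit)) == 1L
  expect_true(keep(sh(e = 1e-25, qcov = 50, pid = 40)))
  expect_false(keep(sh(e = 1e-19, qcov = 50, pid = 40)))
  expect_true(keep(sh(e = 1e-20, qcov = 40, pid = 30)))  # exact boundary
  expect_false(keep(sh(qcov = 39.999)))
  expect_false(keep(sh(pid = 29.999)))
  # family agreement required by default, protein scope relaxes it
  expect_false(keep(sh(family = "GH5")))
  relaxed <- confirm_rules(scope = "protein")
  expect_identical(nrow(confirm_calls(calls, sh(family = "GH5"),
                                      rules = relaxed)), 1L)
  # SUSC/SUSD/GT calls pass through; hmm_only bypasses confirmation
  sus <- data.frame(protein_id = "p2", label = "SUSD", family = "SUSD",
                    evidence = "HMM", e_value = 1e-10, conflict = FALSE,
                    stringsAsFactors = FALSE)
  expect_identical(nrow(confirm_calls(sus, sh(family = "GH5"))), 1L)
  expect_identical(nrow(confirm_calls(calls, sh(family = "GH5"),
                                      mode = "hmm_only")), 1L)
})

test_that("GT families are relabeled and excluded from CAZyme context", {
  calls <- data.frame(
    protein_id = c("p1", "p2", "p3"),
    label = c("GT2", "GH26", "CE2"),
    family = c("GT2", "GH26", "CE2"),
    evidence = "HMM", e_value = 1e-10, conflict = FALSE,
    stringsAsFactors = FALSE)
  out <- label_gt(calls)
  expect_identical(out$label, c("GT", "GH26", "CE2"))

  genes <- toy_genes(c("GT", "CAZ", "CAZ"))
  ann <- toy_annotations(genes, c("GT", "CAZ", "CAZ"),
                         families = c("GT2", "GH26", "CE2"))
  expect_identical(pulcascade:::context_labels(genes, ann),
                   c("GT", "CAZ", "CAZ"))  # CE2 counts as a CAZyme
})

test_that("annotate_genome composes the stages and validates ids", {
  g <- generate_genome(1, 40, n_puls = 1, n_decoys = 1, seed = 11)
  h <- generate_hit_tables(g, noise_config(seed = 11))
  rogue <- h$domain_hits
  rogue$protein_id[1] <- "nonexistent"
  expect_error(annotate_genome(g$genes, rogue, h$search_hits), "nonexistent")

  empty <- h$domain_hits[0, ]
  ann <- annotate_genome(g$genes, empty, h$search_hits)
  expect_identical(nrow(ann), 0L)
  expect_length(gene_labels(ann, g$genes$gene_id[1]), 0L)

  expect_error(annotate_genome(g$genes, h$domain_hits, NULL,
                               mode = "confirmed"), "search hit")
})

test_that("confirmed-mode calls are a subset of HMM-only calls and shrink monotonically", {
  for (s in 1:5) {
    g <- generate_genome(1, 60, n_puls = 1, n_decoys = 2, seed = s)
    h <- generate_hit_tables(g, noise_config(fp_rate = 0.4, fn_rate = 0.1,
                                             near_threshold_fraction = 0.5,
                                             seed = s))
    conf <- annotate_genome(g$genes, h$domain_hits, h$search_hits,
                            mode = "confirmed")
    hmm <- annotate_genome(g$genes, h$domain_hits, h$search_hits,
                           mode = "hmm_only")
    key <- function(x) paste(x$gene_id, x$family)
    expect_true(all(key(conf) %in% key(hmm)))

    # tightening any confirmation threshold never adds a call
    base <- confirm_rules()
    tighter <- list(confirm_rules(max_evalue = 1e-30),
                    confirm_rules(min_qcov = 60),
                    confirm_rules(min_pid = 50))
    for (tr in tighter) {
      tight <- annotate_genome(g$genes, h$domain_hits, h$search_hits,
                               confirm = tr)
      expect_true(all(key(tight) %in% key(conf)))
    }
  }
})
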