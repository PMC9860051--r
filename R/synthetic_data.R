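#' Reference beta-mannan PUL architecture
#'
#' Ordered gene-label layout used by default when planting PULs in synthetic
#' genomes. It mirrors the gene content of the reference beta-mannan locus
#' of the marine flavobacterium model strain: a SusC/D tandem pair, three
#' GH26 beta-mannanases, a GH5 glucanase, a GH27 alpha-galactosidase, a
#' GH130 mannosylglucose phosphorylase and a CE2 esterase, with regulator /
#' transporter genes (label `"NONE"`) interspersed. Both termini carry
#' CAZymes so that zero-noise mining recovers the planted span exactly.
#'
#' @return Character vector of gene labels; CAZy family strings, `"SUSC"`,
#'   `"SUSD"`, or `"NONE"` for genes without a screened function.
#' @export
#' @examples
#' muricauda_architecture()
muricauda_architecture <- function() {
  c("GH130", "GH26", "NONE", "GH26", "GH27",
    "SUSC", "SUSD", "NONE", "GH26", "GH5", "CE2")
}

#' Noise configuration for synthetic hit tables
#'
#' @param fp_rate Probability that a protein without a true screened label
#'   receives a spurious, filter-passing domain hit.
#' @param fn_rate Probability that a true label's hit is dropped entirely.
#' @param near_threshold_fraction Fraction of generated scores placed within
#'   one order of magnitude (e-values) or a few points (coverage, identity)
#'   of the filtering thresholds, on the correct side of their pass/fail
#'   intent.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical tables.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(fp_rate = 0, fn_rate = 0,
                         near_threshold_fraction = 0, seed = 1L) {
  check_fraction(fp_rate, "fp_rate")
  check_fraction(fn_rate, "fn_rate")
  check_fraction(near_threshold_fraction, "near_threshold_fraction")
  check_count(seed, "seed")
  structure(list(fp_rate = fp_rate, fn_rate = fn_rate,
                 near_threshold_fraction = near_threshold_fraction,
                 seed = as.integer(seed)),
            class = "noise_config")
}

decoy_architectures <- function() {
  list(
    lone_pair   = c("SUSC", "SUSD"),                 # pair, no CAZyme nearby
    cazyme_run  = c("GH26", "GH5", "GH27"),          # CAZymes, no pair
    gt_adjacent = c("SUSC", "SUSD", "GT2", "GT4")    # pair flanked by GTs only
  )
}

#' Generate a synthetic genome with planted PULs and decoy clusters
#'
#' Builds gene tables with known ground truth for the mining pipeline. PULs
#' with the requested architecture are planted at random, disjoint positions
#' on a fixed 1 kb coordinate grid (only gene order matters downstream).
#' Decoys cycle through three confounder types: lone SusC/D pairs with no
#' CAZyme within seven genes, CAZyme runs without a SusC/D pair, and
#' GT-only clusters adjacent to a SusC/D pair. Every feature is separated
#' from its neighbours and from contig edges by at least `pad` background
#' genes so planted features cannot interact.
#'
#' @param n_contigs Number of contigs.
#' @param n_genes_per_contig Genes per contig.
#' @param n_puls Number of planted PULs (distributed round-robin over
#'   contigs).
#' @param architecture Ordered label vector for planted PULs; see
#'   [muricauda_architecture()].
#' @param n_decoys Number of decoy clusters.
#' @param seed Integer seed.
#' @param pad Minimum number of background genes between features and
#'   around contig edges. The default exceeds the seven-gene frame so
#'   decoys stay out of reach of planted anchors.
#' @return An object of class `genome_truth`: a list with `genes` (data
#'   frame: `gene_id`, `contig_id`, `order_index`, `start`, `end`,
#'   `strand`, `locus_tag`), `true_labels` (named character vector over all
#'   gene ids), and `planted_puls` (data frame: `contig_id`, `start_index`,
#'   `end_index`, `architecture`).
#' @export
#' @examples
#' g <- generate_genome(1, 60, n_puls = 1, n_decoys = 3, seed = 0)
#' g$planted_puls
generate_genome <- function(n_contigs = 1L, n_genes_per_contig = 60L,
                            n_puls = 1L,
                            architecture = muricauda_architecture(),
                            n_decoys = 0L, seed = 1L, pad = 8L) {
  check_count(n_contigs, "n_contigs", 1L)
  check_count(n_genes_per_contig, "n_genes_per_contig", 1L)
  check_count(n_puls, "n_puls")
  check_count(n_decoys, "n_decoys")
  check_count(pad, "pad", 1L)
  if (!is.character(architecture) || !length(architecture)) {
    stop("`architecture` must be a non-empty character vector of labels",
         call. = FALSE)
  }
  if (sum(architecture == "SUSC") != 1L || sum(architecture == "SUSD") != 1L) {
    stop("`architecture` must contain exactly one SUSC and one SUSD gene",
         call. = FALSE)
  }

  decoys <- decoy_architectures()
  features <- c(
    lapply(seq_len(n_puls), function(i) list(kind = "pul", labels = architecture)),
    lapply(seq_len(n_decoys), function(i) {
      j <- (i - 1L) %% length(decoys) + 1L
      list(kind = names(decoys)[j], labels = decoys[[j]])
    })
  )

  with_seed(seed, {
    # best-fit assignment of features to contigs: each feature costs its
    # length plus one pad; every contig reserves one leading pad
    if (length(features)) {
      features <- features[sample.int(length(features))]
      remaining <- rep(n_genes_per_contig - pad, n_contigs)
      contig_of <- integer(length(features))
      lens <- vapply(features, function(f) length(f$labels), integer(1))
      for (fi in order(-lens)) {
        cost <- lens[fi] + pad
        ci <- which.max(remaining)
        if (remaining[ci] < cost) {
          stop(sprintf(
            "capacity: cannot place a %d-gene feature; largest free contig block is %d gene slot(s) (need %d incl. padding)",
            lens[fi], max(remaining), cost), call. = FALSE)
        }
        contig_of[fi] <- ci
        remaining[ci] <- remaining[ci] - cost
      }
    } else {
      contig_of <- integer(0)
    }

    genes <- vector("list", n_contigs)
    labels <- vector("list", n_contigs)
    planted <- list()

    for (ci in seq_len(n_contigs)) {
      contig_id <- sprintf("ctg%02d", ci)
      feats <- features[contig_of == ci]
      lens <- vapply(feats, function(f) length(f$labels), integer(1))
      need <- sum(lens) + pad * (length(feats) + 1L)
      if (need > n_genes_per_contig) {
        stop(sprintf(
          "capacity: contig %s needs %d gene slots for %d feature(s) plus padding but has %d",
          contig_id, need, length(feats), n_genes_per_contig), call. = FALSE)
      }
      lab <- rep("NONE", n_genes_per_contig)
      # distribute the slack randomly over the (k + 1) inter-feature gaps
      slack <- n_genes_per_contig - need
      k <- length(feats)
      extra <- if (k >= 0L && slack > 0L) {
        as.integer(stats::rmultinom(1, slack, rep(1, k + 1L)))
      } else rep(0L, k + 1L)
      pos <- pad + extra[1L] + 1L
      for (fi in seq_along(feats)) {
        f <- feats[[fi]]
        idx <- pos:(pos + length(f$labels) - 1L)
        lab[idx] <- f$labels
        if (f$kind == "pul") {
          planted[[length(planted) + 1L]] <- data.frame(
            contig_id = contig_id,
            start_index = idx[1L] - 1L,     # 0-based order index
            end_index = idx[length(idx)] - 1L,
            architecture = "planted",
            stringsAsFactors = FALSE)
        }
        pos <- idx[length(idx)] + pad + extra[fi + 1L] + 1L
      }
      ord <- seq_len(n_genes_per_contig) - 1L
      strand <- ifelse(lab == "NONE", sample(c("+", "-"), n_genes_per_contig,
                                             replace = TRUE), "+")
      genes[[ci]] <- data.frame(
        gene_id = sprintf("%s_g%04d", contig_id, ord),
        contig_id = contig_id,
        order_index = ord,
        start = ord * 1000L + 1L,
        end = ord * 1000L + 901L,
        strand = strand,
        locus_tag = sprintf("%s_%05d", toupper(contig_id), ord * 5L),
        stringsAsFactors = FALSE)
      labels[[ci]] <- setNames(lab, genes[[ci]]$gene_id)
    }

    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL
    true_labels <- unlist(labels)
    planted_puls <- if (length(planted)) {
      p <- do.call(rbind, planted)
      p[order_stable(p$contig_id, p$start_index), , drop = FALSE]
    } else {
      data.frame(contig_id = character(0), start_index = integer(0),
                 end_index = integer(0), architecture = character(0),
                 stringsAsFactors = FALSE)
    }
    rownames(planted_puls) <- NULL

    structure(list(genes = genes, true_labels = true_labels,
                   planted_puls = planted_puls,
                   params = list(n_contigs = n_contigs,
                                 n_genes_per_contig = n_genes_per_contig,
                                 n_puls = n_puls, n_decoys = n_decoys,
                                 seed = as.integer(seed), pad = pad)),
              class = "genome_truth")
  })
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("<genome_truth> %d gene(s) on %d contig(s), %d planted PUL(s)\n",
              nrow(x$genes), length(unique(x$genes$contig_id)),
              nrow(x$planted_puls)))
  invisible(x)
}

susd_profiles <- function() c("PF12741.10", "PF12771.10", "PF14322.9", "PF07980.14")

# draw a filter-passing domain hit score set; near-threshold values sit just
# inside the pass region
rdomain_fields <- function(n, near) {
  aln <- sample(90:380, n, replace = TRUE)
  e <- ifelse(near, 10^runif(n, -6, -5.02), 10^runif(n, -30, -8))
  cov <- ifelse(near, runif(n, 0.31, 0.35), runif(n, 0.5, 0.95))
  from <- sample(1:40, n, replace = TRUE)
  data.frame(e_value = e, alignment_length = aln, profile_coverage = cov,
             env_from = from, env_to = from + aln - 1L)
}

#' Generate synthetic domain-hit and search-hit tables
#'
#' Emulates the outputs of an HMM domain scan against CAZy family profiles
#' and of a protein-protein sequence search against a CAZy database, for a
#' synthetic genome with known labels. Every true label yields a hit set
#' that passes the downstream filters with probability `1 - fn_rate`;
#' proteins without a screened label receive a spurious, HMM-filter-passing
#' domain hit with probability `fp_rate`. Spurious hits are never given
#' confirming search evidence: their search hit either fails one
#' confirmation threshold or is absent, so dual-evidence annotation rejects
#' them while HMM-only annotation retains them.
#'
#' @param truth A `genome_truth` object from [generate_genome()].
#' @param noise A [noise_config()].
#' @return A list with `domain_hits`, `search_hits` (data frames matching
#'   the [filter_domain_hits()] / [confirm_calls()] input contracts) and
#'   `intents` (one row per generated hit set: `protein_id`, `family`,
#'   `type` = `"true"`/`"fp"`, `hmm_pass`, `confirm_pass`).
#' @export
generate_hit_tables <- function(truth, noise = noise_config()) {
  stopifnot(inherits(truth, "genome_truth"))
  if (!inherits(noise, "noise_config")) {
    stop("`noise` must be created by noise_config()", call. = FALSE)
  }
  labels <- truth$true_labels
  with_seed(noise$seed, {
    ids <- names(labels)
    is_true <- labels != "NONE"
    kept <- is_true & runif(length(labels)) >= noise$fn_rate
    t_ids <- ids[kept]
    t_lab <- labels[kept]
    nt <- length(t_ids)
    near_t <- runif(nt) < noise$near_threshold_fraction

    profile <- ifelse(t_lab == "SUSC", "TIGR04056",
               ifelse(t_lab == "SUSD",
                      sample(susd_profiles(), nt, replace = TRUE), t_lab))
    dom_true <- cbind(data.frame(protein_id = t_ids, profile_name = profile,
                                 stringsAsFactors = FALSE),
                      rdomain_fields(nt, near_t))

    # confirming search hits for true CAZy-family labels (GT families bypass
    # confirmation downstream, SUSC/SUSD are HMM-only by construction)
    cz <- !(t_lab %in% c("SUSC", "SUSD")) & !grepl("^GT", t_lab)
    ncz <- sum(cz)
    near_s <- runif(ncz) < noise$near_threshold_fraction
    search_true <- data.frame(
      query_id = t_ids[cz],
      subject_id = sprintf("cazydb|%s|%05d", t_lab[cz],
                           sample.int(99999L, ncz, replace = TRUE)),
      subject_family = t_lab[cz],
      percent_identity = ifelse(near_s, runif(ncz, 30, 33), runif(ncz, 40, 95)),
      query_coverage = ifelse(near_s, runif(ncz, 40, 44), runif(ncz, 60, 100)),
      e_value = ifelse(near_s, 10^runif(ncz, -21, -20), 10^runif(ncz, -80, -30)),
      stringsAsFactors = FALSE)

    # spurious domain hits on unlabeled proteins
    fp_ids <- ids[!is_true & runif(length(labels)) < noise$fp_rate]
    nf <- length(fp_ids)
    fp_fam <- sample(c("GH10", "GH16", "GH3", "CE6", "GH43", "GH95"),
                     nf, replace = TRUE)
    near_f <- runif(nf) < noise$near_threshold_fraction
    dom_fp <- cbind(data.frame(protein_id = fp_ids, profile_name = fp_fam,
                               stringsAsFactors = FALSE),
                    rdomain_fields(nf, near_f))

    # half of the spurious hits get a near-miss search hit that fails exactly
    # one confirmation threshold; the rest get none
    has_sh <- runif(nf) < 0.5
    nf2 <- sum(has_sh)
    fail_field <- sample(c("e", "pid", "qcov"), nf2, replace = TRUE)
    search_fp <- data.frame(
      query_id = fp_ids[has_sh],
      subject_id = sprintf("cazydb|%s|%05d", fp_fam[has_sh],
                           sample.int(99999L, nf2, replace = TRUE)),
      subject_family = fp_fam[has_sh],
      percent_identity = ifelse(fail_field == "pid", runif(nf2, 20, 29.9),
                                runif(nf2, 40, 95)),
      query_coverage = ifelse(fail_field == "qcov", runif(nf2, 10, 39),
                              runif(nf2, 60, 100)),
      e_value = ifelse(fail_field == "e", 10^runif(nf2, -19.9, -18),
                       10^runif(nf2, -80, -30)),
      stringsAsFactors = FALSE)

    domain_hits <- rbind(dom_true, dom_fp)
    search_hits <- rbind(search_true, search_fp)
    domain_hits <- domain_hits[order_stable(domain_hits$protein_id,
                                            domain_hits$profile_name), ]
    search_hits <- search_hits[order_stable(search_hits$query_id,
                                            search_hits$subject_family), ]
    rownames(domain_hits) <- rownames(search_hits) <- NULL

    intents <- rbind(
      data.frame(protein_id = t_ids, family = t_lab,
                 type = rep("true", nt), hmm_pass = rep(TRUE, nt),
                 confirm_pass = rep(TRUE, nt), stringsAsFactors = FALSE),
      data.frame(protein_id = fp_ids, family = fp_fam,
                 type = rep("fp", nf), hmm_pass = rep(TRUE, nf),
                 confirm_pass = rep(FALSE, nf), stringsAsFactors = FALSE))
    rownames(intents) <- NULL

    list(domain_hits = domain_hits, search_hits = search_hits,
         intents = intents)
  })
}

#' Generate a synthetic iBAQ intensity matrix with planted effects
#'
#' Protein intensities are lognormal around a protein-specific base
#' abundance (base-10 dynamic range of roughly four orders of magnitude,
#' as typical for whole-cell proteomes); replicate scatter is controlled by
#' the coefficient of variation `cv`. Effect proteins are multiplied by
#' `effect_fold` in the first condition. Missingness is applied uniformly
#' at random per cell.
#'
#' @param n_proteins Number of proteins.
#' @param conditions Character vector of condition labels; the first is the
#'   induced/reference condition.
#' @param n_reps Replicates per condition (>= 2).
#' @param effect_proteins Indices or protein ids receiving the fold change.
#' @param effect_fold Fold change (> 0) applied in the first condition.
#' @param cv Coefficient of variation of replicate intensities.
#' @param missing_rate Per-cell probability of a missing value.
#' @param seed Integer seed.
#' @param base_spread Standard deviation (natural log scale) of the
#'   protein base abundances.
#' @return A list with `intensities` (proteins x samples matrix, `NA` for
#'   missing), `metadata` (data frame: `sample_id`, `condition`,
#'   `replicate`) and `truth` (data frame: `protein_id`, `is_effect`).
#'   When `effect_fold == 1` no protein is flagged as a true positive.
#' @export
generate_proteome <- function(n_proteins, conditions = c("galactomannan",
                                                         "pectin", "mannose"),
                              n_reps = 3L, effect_proteins = integer(0),
                              effect_fold = 1, cv = 0.2, missing_rate = 0,
                              seed = 1L, base_spread = 1.5) {
  check_count(n_proteins, "n_proteins", 1L)
  check_count(n_reps, "n_reps", 2L)
  check_fraction(missing_rate, "missing_rate")
  if (!is.numeric(effect_fold) || length(effect_fold) != 1L || effect_fold <= 0) {
    stop("`effect_fold` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (length(conditions) < 2L) {
    stop("at least two conditions are required", call. = FALSE)
  }

  ids <- sprintf("prot%05d", seq_len(n_proteins))
  eff_idx <- if (is.character(effect_proteins)) {
    match(effect_proteins, ids)
  } else as.integer(effect_proteins)
  if (anyNA(eff_idx) || any(eff_idx < 1L | eff_idx > n_proteins)) {
    stop("`effect_proteins` must index proteins in the matrix", call. = FALSE)
  }

  n_samp <- length(conditions) * n_reps
  metadata <- data.frame(
    sample_id = paste(rep(conditions, each = n_reps),
                      rep(seq_len(n_reps), length(conditions)), sep = "_"),
    condition = rep(conditions, each = n_reps),
    replicate = rep(seq_len(n_reps), length(conditions)),
    stringsAsFactors = FALSE)

  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    base <- exp(log(1e6) + rnorm(n_proteins, 0, base_spread))
    m <- matrix(rlnorm(n_proteins * n_samp, meanlog = rep(log(base), n_samp),
                       sdlog = sdlog),
                nrow = n_proteins, ncol = n_samp,
                dimnames = list(ids, metadata$sample_id))
    first <- metadata$condition == conditions[1L]
    if (length(eff_idx) && effect_fold != 1) {
      m[eff_idx, first] <- m[eff_idx, first] * effect_fold
    }
    if (missing_rate > 0) {
      m[matrix(runif(length(m)) < missing_rate, nrow = n_proteins)] <- NA_real_
    }
    truth <- data.frame(protein_id = ids, is_effect = FALSE,
                        stringsAsFactors = FALSE)
    if (effect_fold != 1) truth$is_effect[eff_idx] <- TRUE
    list(intensities = m, metadata = metadata, truth = truth)
  })
}

#' Generate synthetic carbohydrate microarray spot tables
#'
#' Each (extract, probe) pair gets a base mean signal shared across
#' treatments; the buffer-control treatment (the first element of
#' `treatments`) is never deleted. Signals of targeted (extract, probe)
#' cells under their named treatment are multiplied by
#' `1 - deletion_depth` before replicate noise is applied.
#'
#' @param n_extracts,n_probes Grid dimensions.
#' @param treatments Character vector; the first entry is the buffer
#'   control.
#' @param deletion_targets Data frame with columns `extract_id`,
#'   `probe_id`, `treatment` naming the planted epitope deletions. The
#'   control treatment cannot be targeted.
#' @param deletion_depth Fractional signal loss in `[0, 1]` applied to
#'   targeted cells.
#' @param n_spots Replicate spots per cell (>= 2).
#' @param noise_cv Coefficient of variation of replicate spot noise; `0`
#'   gives the noise-free mode used for exact checks.
#' @param seed Integer seed.
#' @return A list with `spots` (data frame: `extract_id`, `probe_id`,
#'   `treatment`, `replicate`, `signal`) and `truth` (the deletion targets
#'   with the applied `deletion_depth`).
#' @export
generate_arrays <- function(n_extracts, n_probes,
                            treatments = c("buffer", "GH26C"),
                            deletion_targets = NULL, deletion_depth = 1,
                            n_spots = 2L, noise_cv = 0, seed = 1L) {
  check_count(n_extracts, "n_extracts", 1L)
  check_count(n_probes, "n_probes", 1L)
  check_count(n_spots, "n_spots", 2L)
  check_fraction(deletion_depth, "deletion_depth")
  if (length(treatments) < 2L) {
    stop("need a control plus at least one treatment", call. = FALSE)
  }
  control <- treatments[1L]
  extracts <- sprintf("extract%02d", seq_len(n_extracts))
  probes <- sprintf("probe%02d", seq_len(n_probes))
  if (is.null(deletion_targets)) {
    deletion_targets <- data.frame(extract_id = character(0),
                                   probe_id = character(0),
                                   treatment = character(0),
                                   stringsAsFactors = FALSE)
  }
  check_columns(deletion_targets, c("extract_id", "probe_id", "treatment"),
                "`deletion_targets`")
  if (any(deletion_targets$treatment == control)) {
    stop("the buffer control treatment cannot carry planted deletions",
         call. = FALSE)
  }

  with_seed(seed, {
    base <- matrix(runif(n_extracts * n_probes, 20, 100),
                   n_extracts, n_probes, dimnames = list(extracts, probes))
    cells <- expand.grid(extract_id = extracts, probe_id = probes,
                         treatment = treatments, replicate = seq_len(n_spots),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- base[cbind(cells$extract_id, cells$probe_id)]
    key <- paste(cells$extract_id, cells$probe_id, cells$treatment)
    tkey <- paste(deletion_targets$extract_id, deletion_targets$probe_id,
                  deletion_targets$treatment)
    hit <- key %in% tkey
    mu[hit] <- mu[hit] * (1 - deletion_depth)
    signal <- if (noise_cv > 0) {
      mu * rlnorm(length(mu), meanlog = -log(1 + noise_cv^2) / 2,
                  sdlog = sqrt(log(1 + noise_cv^2)))
    } else mu
    cells$signal <- signal
    cells <- cells[order_stable(cells$extract_id, cells$probe_id,
                                cells$treatment, cells$replicate), ]
    rownames(cells) <- NULL
    truth <- deletion_targets
    truth$deletion_depth <- rep(deletion_depth, nrow(truth))
    list(spots = cells, truth = truth)
  })
}
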