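# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# Fixed-point set-closure formulation of the seven-gene-frame rule: grow the
# span by absorbing any non-GT CAZyme within `frame` genes of the current
# span edge, until nothing changes; then trim termini to CAZyme/SusC/SusD.
oracle_extend <- function(labels, anchor_lo, anchor_hi, frame = 7) {
  if (is.numeric(labels)) {
    labels <- names(pulcascade:::label_code)[match(labels,
                                                   pulcascade:::label_code)]
  }
  caz <- which(labels == "CAZ")
  lo <- anchor_lo; hi <- anchor_hi
  repeat {
    add <- caz[(caz >= lo - frame & caz < lo) | (caz > hi & caz <= hi + frame)]
    if (!length(add)) break
    lo <- min(lo, add); hi <- max(hi, add)
  }
  keep <- c("CAZ", "SUSC", "SUSD")
  while (lo < anchor_lo && !(labels[lo] %in% keep)) lo <- lo + 1
  while (hi > anchor_hi && !(labels[hi] %in% keep)) hi <- hi - 1
  c(as.integer(lo), as.integer(hi))
}

# Vectorized one-sided closure boundary over a matrix of flank codes
# (rows = arrangements, columns = positions beyond the anchor edge;
# code 1 = CAZ). Returns the farthest absorbed offset per row (0 = none).
oracle_extend_flanks <- function(M, frame = 7) {
  b <- rep(0L, nrow(M))
  for (j in seq_len(ncol(M))) {
    upd <- M[, j] == 1L & (j - b) <= frame
    b[upd] <- j
  }
  b
}

# Independent SusC/D pairing: repeatedly pick the candidate pair with the
# smallest (left position, gap) among genes not yet used.
oracle_pairs <- function(labels, strands = NULL, max_gap = 1,
                         same_strand = TRUE) {
  n <- length(labels)
  if (is.null(strands)) strands <- rep("+", n)
  used <- logical(n)
  pairs <- list()
  repeat {
    best <- NULL
    for (i in seq_len(n)) {
      if (used[i] || !(labels[i] %in% c("SUSC", "SUSD"))) next
      for (j in seq_len(n)) {
        if (j <= i || used[j] || j - i - 1 > max_gap) next
        if (!(labels[j] %in% c("SUSC", "SUSD")) || labels[j] == labels[i]) next
        if (same_strand && strands[i] != strands[j]) next
        if (is.null(best) || i < best[1] || (i == best[1] && j < best[2])) {
          best <- c(i, j)
        }
      }
    }
    if (is.null(best)) break
    used[best] <- TRUE
    pairs[[length(pairs) + 1]] <- best
  }
  pairs
}

# Longest strictly increasing subsequence by exhaustive subset enumeration
# (for small n only).
oracle_lis <- function(y) {
  n <- length(y)
  if (!n) return(0L)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    v <- y[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# Build a minimal gene table for a label arrangement on one contig.
toy_genes <- function(labels, strands = NULL, contig = "ctgA") {
  n <- length(labels)
  if (is.null(strands)) strands <- rep("+", n)
  data.frame(
    gene_id = sprintf("%s_g%03d", contig, seq_len(n) - 1L),
    contig_id = contig,
    order_index = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 901L,
    strand = strands,
    locus_tag = sprintf("%s_%03d", contig, seq_len(n)),
    stringsAsFactors = FALSE)
}

# Annotation calls matching a label arrangement ("CAZ" becomes GH26 unless
# family is supplied per position via `families`).
toy_annotations <- function(genes, labels, families = NULL) {
  sel <- which(labels != "NONE")
  if (!length(sel)) {
    calls <- data.frame(gene_id = character(0), label = character(0),
                        family = character(0), evidence = character(0),
                        e_value = numeric(0), conflict = logical(0),
                        stringsAsFactors = FALSE)
  } else {
    fam <- if (is.null(families)) {
      ifelse(labels[sel] == "CAZ", "GH26",
             ifelse(labels[sel] == "GT", "GT2", labels[sel]))
    } else families[sel]
    lab <- ifelse(labels[sel] %in% c("SUSC", "SUSD"), labels[sel],
                  ifelse(grepl("^GT", fam), "GT", fam))
    calls <- data.frame(gene_id = genes$gene_id[sel], label = lab,
                        family = fam, evidence = "HMM",
                        e_value = 1e-30, conflict = FALSE,
                        stringsAsFactors = FALSE)
  }
  class(calls) <- c("annotation_calls", "data.frame")
  attr(calls, "gene_ids") <- genes$gene_id
  calls
}

# A quick pul-like stub for comparative-module tests.
toy_pul <- function(families, gene_ids = NULL, contig = "ctgA") {
  structure(list(contig_id = contig,
                 span = c(start_index = 0L,
                          end_index = length(families) - 1L),
                 anchors = list(c(susc = "sc", susd = "sd")),
                 gene_ids = gene_ids %||% sprintf("g%02d", seq_along(families)),
                 cazyme_calls = data.frame(
                   gene_id = sprintf("g%02d", seq_along(families)),
                   family = families, stringsAsFactors = FALSE),
                 family_set = sort(unique(families)),
                 n_genes = length(families), merged = FALSE),
            class = "pul")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# enumerate all label vectors of length k over the given alphabet codes
enum_flanks <- function(k, alphabet = 0:2) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  M <- as.matrix(expand.grid(rep(list(alphabet), k), KEEP.OUT.ATTRS = FALSE))
  storage.mode(M) <- "integer"
  dimnames(M) <- NULL
  M
}
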