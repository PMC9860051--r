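gene_table_cols <- c("gene_id", "contig_id", "order_index", "start", "end",
                     "strand")

validate_genes <- function(genes) {
  check_columns(genes, gene_table_cols, "gene table")
  if (anyDuplicated(genes$gene_id)) {
    stop("gene ids must be unique", call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene start must be <= end", call. = FALSE)
  }
  invisible(genes)
}

# context label per gene: SUSC, SUSD, CAZ (non-GT CAZyme), GT, or NONE;
# transporter/lipoprotein roles take precedence over residual CAZyme calls
context_labels <- function(genes, annotations) {
  lab <- rep("NONE", nrow(genes))
  if (!nrow(annotations)) return(lab)
  idx <- split(annotations$label, annotations$gene_id)
  m <- match(genes$gene_id, names(idx))
  has <- !is.na(m)
  lab[has] <- vapply(idx[m[has]], function(l) {
    if ("SUSC" %in% l) "SUSC"
    else if ("SUSD" %in% l) "SUSD"
    else if (any(!(l %in% c("GT", "SUSC", "SUSD")))) "CAZ"
    else "GT"
  }, character(1))
  lab
}

#' Find SusC/D anchor pairs
#'
#' Scans each contig in gene order for (SusC, SusD) gene pairs with at most
#' `max_gap` intervening genes (either orientation along the contig), on
#' the same strand when `require_same_strand` is set. Each gene is used in
#' at most one pair; candidate pairs are taken greedily left to right with
#' the closest pair winning ties.
#'
#' @param genes Gene table (see [generate_genome()] for the layout).
#' @param annotations `annotation_calls` from [annotate_genome()].
#' @param max_gap Maximum number of intervening genes (default 1).
#' @param require_same_strand Require both genes on one strand.
#' @return Data frame with one row per anchor: `contig_id`, `susc_id`,
#'   `susd_id`, `lo_index`, `hi_index` (0-based order indices of the pair
#'   span), `strand`.
#' @export
find_suscd_pairs <- function(genes, annotations, max_gap = 1L,
                             require_same_strand = TRUE) {
  validate_genes(genes)
  check_count(max_gap, "max_gap")
  empty <- data.frame(contig_id = character(0), susc_id = character(0),
                      susd_id = character(0), lo_index = integer(0),
                      hi_index = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  out <- list()
  for (ctg in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$order_index), , drop = FALSE]
    lab <- context_labels(g, annotations)
    cand_pos <- which(lab %in% c("SUSC", "SUSD"))
    if (length(cand_pos) < 2L) next
    # enumerate candidate pairs, ordered left-to-right then by gap
    cand <- list()
    for (a in seq_along(cand_pos)) {
      for (b in seq_along(cand_pos)) {
        if (b <= a) next
        i <- cand_pos[a]; j <- cand_pos[b]
        if (j - i - 1L > max_gap) next
        if (lab[i] == lab[j]) next
        if (require_same_strand && g$strand[i] != g$strand[j]) next
        cand[[length(cand) + 1L]] <- c(i = i, j = j)
      }
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, "i"], cm[, "j"] - cm[, "i"]), , drop = FALSE]
    used <- logical(nrow(g))
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (used[i] || used[j]) next
      used[c(i, j)] <- TRUE
      susc <- if (lab[i] == "SUSC") i else j
      susd <- if (lab[i] == "SUSC") j else i
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, susc_id = g$gene_id[susc], susd_id = g$gene_id[susd],
        lo_index = g$order_index[i], hi_index = g$order_index[j],
        strand = g$strand[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

label_code <- c(NONE = 0L, CAZ = 1L, GT = 2L, SUSC = 3L, SUSD = 4L)

#' Extend a PUL span over a gene-label vector
#'
#' The span-extension kernel behind [extract_pul()], exposed for direct use
#' on label sequences. Starting from the anchor span, each side repeatedly
#' examines the next `frame` genes; if any carries a non-GT CAZyme label
#' (`"CAZ"`), the boundary jumps to the farthest such gene within the
#' window and the window is re-examined from there (`"iterative"` mode; a
#' `"fixed"` mode stops after the first window). Extension stops when a
#' window holds no CAZyme or at the contig end. The final span is trimmed
#' so that each terminus is a CAZyme, SusC or SusD gene.
#'
#' @param labels Character vector over `names(label_code)` (`"NONE"`,
#'   `"CAZ"`, `"GT"`, `"SUSC"`, `"SUSD"`) or the equivalent integer codes
#'   0--4.
#' @param anchor_lo,anchor_hi 1-based positions of the anchor span within
#'   `labels`.
#' @param frame Window size in genes (default 7).
#' @param window `"iterative"` (default) or `"fixed"` window semantics.
#' @return Integer vector `c(lo, hi)` of 1-based span positions.
#' @export
#' @examples
#' pul_extend_labels(c("NONE", "CAZ", "NONE", "NONE", "SUSC", "SUSD"), 5, 6)
pul_extend_labels <- function(labels, anchor_lo, anchor_hi, frame = 7L,
                              window = c("iterative", "fixed")) {
  window <- match.arg(window)
  codes <- if (is.numeric(labels)) as.integer(labels)
           else unname(label_code[labels])
  if (anyNA(codes)) stop("unknown label in `labels`", call. = FALSE)
  n <- length(codes)
  if (anchor_lo < 1L || anchor_hi > n || anchor_lo > anchor_hi) {
    stop("anchor span out of range", call. = FALSE)
  }
  frame <- check_count(frame, "frame", 1L)
  anchor_lo <- as.integer(anchor_lo)
  anchor_hi <- as.integer(anchor_hi)

  hi <- anchor_hi
  repeat {
    top <- min(hi + frame, n)
    if (top <= hi) break
    win <- codes[(hi + 1L):top]
    cz <- which(win == 1L)
    if (!length(cz)) break
    hi <- hi + cz[length(cz)]
    if (window == "fixed") break
  }
  lo <- anchor_lo
  repeat {
    bot <- max(lo - frame, 1L)
    if (bot >= lo) break
    win <- codes[bot:(lo - 1L)]
    cz <- which(win == 1L)
    if (!length(cz)) break
    lo <- bot + cz[1L] - 1L
    if (window == "fixed") break
  }
  # trim: each terminus must be a CAZyme, SusC or SusD gene
  while (lo < anchor_lo && !(codes[lo] %in% c(1L, 3L, 4L))) lo <- lo + 1L
  while (hi > anchor_hi && !(codes[hi] %in% c(1L, 3L, 4L))) hi <- hi - 1L
  c(lo = lo, hi = hi)
}

new_pul <- function(genes_ctg, lab, lo_pos, hi_pos, anchors, annotations) {
  span_genes <- genes_ctg$gene_id[lo_pos:hi_pos]
  caz <- annotations[annotations$gene_id %in% span_genes &
                       !(annotations$label %in% c("GT", "SUSC", "SUSD")), ,
                     drop = FALSE]
  caz <- caz[order_stable(match(caz$gene_id, span_genes), caz$family), ,
             drop = FALSE]
  structure(list(
    contig_id = genes_ctg$contig_id[1L],
    span = c(start_index = genes_ctg$order_index[lo_pos],
             end_index = genes_ctg$order_index[hi_pos]),
    anchors = anchors,
    gene_ids = span_genes,
    cazyme_calls = data.frame(gene_id = caz$gene_id, family = caz$family,
                              stringsAsFactors = FALSE),
    family_set = sort(unique(caz$family)),
    n_genes = length(span_genes),
    merged = length(anchors) > 1L
  ), class = "pul")
}

#' @export
print.pul <- function(x, ...) {
  cat(sprintf("<pul> %s[%d..%d] %d gene(s); families: %s\n",
              x$contig_id, x$span[1L], x$span[2L], x$n_genes,
              if (length(x$family_set)) paste(x$family_set, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Extract a PUL around one SusC/D anchor
#'
#' Applies the seven-gene-frame genetic-context rule around an anchor pair:
#' see [pul_extend_labels()] for the window semantics. Glycosyl
#' transferases never extend the span.
#'
#' @param anchor One row of the data frame returned by
#'   [find_suscd_pairs()] (data frame or list with `contig_id`,
#'   `susc_id`, `susd_id`, `lo_index`, `hi_index`).
#' @param genes Gene table.
#' @param annotations `annotation_calls` from [annotate_genome()].
#' @param frame Window size in genes (default 7).
#' @param window Window semantics, see [pul_extend_labels()].
#' @return A `pul` object: contig, order-index span, anchor gene ids,
#'   ordered CAZyme calls and the family set (GT labels excluded).
#' @export
extract_pul <- function(anchor, genes, annotations, frame = 7L,
                        window = c("iterative", "fixed")) {
  window <- match.arg(window)
  validate_genes(genes)
  g <- genes[genes$contig_id == anchor$contig_id, , drop = FALSE]
  g <- g[order(g$order_index), , drop = FALSE]
  lab <- context_labels(g, annotations)
  lo_pos <- match(anchor$lo_index, g$order_index)
  hi_pos <- match(anchor$hi_index, g$order_index)
  if (is.na(lo_pos) || is.na(hi_pos)) {
    stop("anchor indices not found on contig", call. = FALSE)
  }
  span <- pul_extend_labels(lab, lo_pos, hi_pos, frame, window)
  new_pul(g, lab, span[1L], span[2L],
          anchors = list(c(susc = anchor$susc_id, susd = anchor$susd_id)),
          annotations = annotations)
}

#' Keep PULs containing a required CAZyme family
#'
#' Implements the assembly screen: putative clusters are retained only if
#' their family set contains the required family (any subfamily counts,
#' e.g. `GH26_1` matches `GH26`).
#'
#' @param puls A list of `pul` objects (or a `pul_set`).
#' @param required_family Family that must be present (default `"GH26"`).
#' @return The retained PULs, with a `screen_summary` attribute giving
#'   kept/dropped counts.
#' @export
screen_filter <- function(puls, required_family = "GH26") {
  pat <- paste0("^", required_family, "($|_)")
  has <- vapply(puls, function(p) any(grepl(pat, p$family_set)), logical(1))
  out <- puls[has]
  attr(out, "screen_summary") <- data.frame(kept = sum(has),
                                            dropped = sum(!has))
  class(out) <- class(puls)
  out
}

#' Mine an assembly for beta-mannan PULs
#'
#' Full detection pass over one assembly: SusC/D anchor pairing, seven-gene
#' frame extension around each anchor, merging of overlapping spans from
#' distinct anchors, and the GH26 screen filter. Results are deterministic
#' and reported in contig/coordinate order.
#'
#' @param genes Gene table.
#' @param annotations `annotation_calls` from [annotate_genome()].
#' @param frame Window size in genes.
#' @param max_gap Maximum genes between SusC and SusD in an anchor.
#' @param require_same_strand Anchor strand rule.
#' @param require_gh26 Apply the GH26 cluster screen; set `FALSE` to keep
#'   all anchored clusters.
#' @param window Window semantics, see [pul_extend_labels()].
#' @return A `pul_set`: list of `pul` objects with an `as.data.frame`
#'   method.
#' @export
mine_assembly <- function(genes, annotations, frame = 7L, max_gap = 1L,
                          require_same_strand = TRUE, require_gh26 = TRUE,
                          window = c("iterative", "fixed")) {
  window <- match.arg(window)
  validate_genes(genes)
  anchors <- find_suscd_pairs(genes, annotations, max_gap,
                              require_same_strand)
  puls <- list()
  for (ctg in unique(anchors$contig_id)) {
    g <- genes[genes$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$order_index), , drop = FALSE]
    lab <- context_labels(g, annotations)
    rows <- which(anchors$contig_id == ctg)
    spans <- t(vapply(rows, function(r) {
      pul_extend_labels(lab, match(anchors$lo_index[r], g$order_index),
                        match(anchors$hi_index[r], g$order_index),
                        frame, window)
    }, integer(2)))
    anc <- lapply(rows, function(r) c(susc = anchors$susc_id[r],
                                      susd = anchors$susd_id[r]))
    # merge intersecting spans from distinct anchors
    ord <- order(spans[, 1L], spans[, 2L])
    spans <- spans[ord, , drop = FALSE]
    anc <- anc[ord]
    merged <- list()
    cur_lo <- spans[1L, 1L]; cur_hi <- spans[1L, 2L]; cur_anc <- anc[1L]
    if (nrow(spans) > 1L) {
      for (r in 2L:nrow(spans)) {
        if (spans[r, 1L] <= cur_hi) {
          cur_hi <- max(cur_hi, spans[r, 2L])
          cur_anc <- c(cur_anc, anc[r])
        } else {
          merged[[length(merged) + 1L]] <- list(lo = cur_lo, hi = cur_hi,
                                                anchors = cur_anc)
          cur_lo <- spans[r, 1L]; cur_hi <- spans[r, 2L]; cur_anc <- anc[r]
        }
      }
    }
    merged[[length(merged) + 1L]] <- list(lo = cur_lo, hi = cur_hi,
                                          anchors = cur_anc)
    for (m in merged) {
      puls[[length(puls) + 1L]] <- new_pul(g, lab, m$lo, m$hi, m$anchors,
                                           annotations)
    }
  }
  if (require_gh26) {
    puls <- screen_filter(puls)
    summary <- attr(puls, "screen_summary")
  } else {
    summary <- data.frame(kept = length(puls), dropped = 0L)
  }
  ord <- order_stable(vapply(puls, `[[`, character(1), "contig_id"),
                      vapply(puls, function(p) p$span[[1L]], numeric(1)))
  out <- puls[ord]
  attributes(out) <- NULL
  attr(out, "screen_summary") <- summary
  class(out) <- "pul_set"
  out
}

#' @export
print.pul_set <- function(x, ...) {
  cat(sprintf("<pul_set> %d PUL(s)\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' @export
as.data.frame.pul_set <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(contig_id = character(0), start_index = integer(0),
                      end_index = integer(0), susc_id = character(0),
                      susd_id = character(0), n_genes = integer(0),
                      n_cazymes = integer(0), families = character(0),
                      merged = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(p) data.frame(
    contig_id = p$contig_id,
    start_index = unname(p$span[1L]),
    end_index = unname(p$span[2L]),
    susc_id = p$anchors[[1L]][["susc"]],
    susd_id = p$anchors[[1L]][["susd"]],
    n_genes = p$n_genes,
    n_cazymes = nrow(p$cazyme_calls),
    families = paste(p$family_set, collapse = ","),
    merged = p$merged,
    stringsAsFactors = FALSE)))
}
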