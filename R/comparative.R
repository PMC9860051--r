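#' Reference PUL module definition
#'
#' The CAZyme family content of the reference beta-mannan PUL used for
#' modularity classification and repertoire matching: GH26 beta-mannanases,
#' a GH5 glucanase, a GH27 alpha-galactosidase, a GH130 mannosylglucose
#' phosphorylase and a CE2 esterase, together with the SusC/D pair.
#'
#' @param families Required CAZy families; must contain GH26.
#' @param components Required non-CAZyme components.
#' @return A list of class `reference_module`.
#' @export
reference_module <- function(families = c("GH26", "GH5", "GH27", "GH130", "CE2"),
                             components = c("SUSC", "SUSD")) {
  if (!length(families) || !any(grepl("^GH26($|_)", families))) {
    stop("reference families must be non-empty and include GH26", call. = FALSE)
  }
  structure(list(families = families, components = components),
            class = "reference_module")
}

# collapse listed families' subfamily labels (e.g. GH5_26 -> GH5)
collapse_subfamilies <- function(families, collapse = "GH5") {
  for (f in collapse) {
    families[grepl(paste0("^", f, "_"), families)] <- f
  }
  families
}

#' Does a PUL have the same modularity as the reference?
#'
#' Default mode: set equality between the PUL's CAZyme family set and the
#' reference families, at (sub)family level with GH5 subfamilies collapsed
#' to GH5; multiplicity is ignored and extra families disqualify. Superset
#' mode only requires every reference family to be present.
#'
#' @param pul A `pul` object, or a character vector of family labels.
#' @param reference A [reference_module()].
#' @param mode `"equal"` (default) or `"superset"`.
#' @param collapse Families whose subfamily labels are collapsed before
#'   comparison.
#' @return Logical scalar.
#' @export
same_modularity <- function(pul, reference = reference_module(),
                            mode = c("equal", "superset"),
                            collapse = "GH5") {
  mode <- match.arg(mode)
  fams <- if (is.character(pul)) pul else pul$family_set
  fams <- unique(collapse_subfamilies(fams, collapse))
  ref <- unique(collapse_subfamilies(reference$families, collapse))
  if (mode == "equal") setequal(fams, ref) else all(ref %in% fams)
}

#' Family co-occurrence across a PUL set
#'
#' For every CAZyme family, the fraction of PULs whose family set contains
#' it. The full table is always returned; rows at or above `min_fraction`
#' are marked `retained` (the "at least 5 percent of screened clusters"
#' view is the retained subset).
#'
#' @param puls A `pul_set` or list of `pul` objects.
#' @param min_fraction Retention threshold (inclusive).
#' @return Data frame with `family`, `count`, `fraction`, `retained`,
#'   ordered by decreasing fraction.
#' @export
cooccurrence <- function(puls, min_fraction = 0.05) {
  check_fraction(min_fraction, "min_fraction")
  n <- length(puls)
  if (!n) {
    return(data.frame(family = character(0), count = integer(0),
                      fraction = numeric(0), retained = logical(0),
                      stringsAsFactors = FALSE))
  }
  fams <- unlist(lapply(puls, function(p) unique(p$family_set)))
  tab <- table(fams)
  out <- data.frame(family = names(tab), count = as.integer(tab),
                    fraction = as.integer(tab) / n,
                    stringsAsFactors = FALSE)
  out$retained <- out$fraction >= min_fraction
  out <- out[order_stable(-out$fraction, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Counts of distinct family sets
#'
#' Underlying counts of an UpSet-style intersection plot: how many PULs
#' share each exact family set. Counts form an exact partition of the PUL
#' set.
#'
#' @param puls A `pul_set` or list of `pul` objects.
#' @return Data frame with `family_set` (families joined by `+`, empty
#'   string for none) and `count`.
#' @export
intersection_counts <- function(puls) {
  keys <- vapply(puls, function(p) paste(sort(unique(p$family_set)),
                                         collapse = "+"), character(1))
  tab <- table(keys)
  out <- data.frame(family_set = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order_stable(-out$count, out$family_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repertoire matching for metagenome-assembled genomes
#'
#' MAG screening ignores genetic context: labels are counted anywhere in
#' the genome. The minimal criterion requires at least one SusC, one SusD
#' and one GH26; the full criterion additionally requires every reference
#' family to be present somewhere in the genome.
#'
#' @param annotations `annotation_calls` for the whole genome.
#' @param reference A [reference_module()].
#' @param collapse Subfamily collapsing, as in [same_modularity()].
#' @return List with logical elements `minimal` and `full`.
#' @export
mag_repertoire_match <- function(annotations, reference = reference_module(),
                                 collapse = "GH5") {
  fams <- unique(collapse_subfamilies(
    annotations$family[!(annotations$label %in% c("SUSC", "SUSD", "GT"))],
    collapse))
  has_susc <- any(annotations$label == "SUSC")
  has_susd <- any(annotations$label == "SUSD")
  has_gh26 <- any(grepl("^GH26($|_)", fams))
  ref <- unique(collapse_subfamilies(reference$families, collapse))
  list(minimal = has_susc && has_susd && has_gh26,
       full = all(ref %in% fams))
}

# length of the longest strictly increasing subsequence (O(n^2))
lis_length <- function(y) {
  n <- length(y)
  if (!n) return(0L)
  d <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (y[j] < y[i] && d[j] + 1L > d[i]) d[i] <- d[j] + 1L
    }
  }
  max(d)
}

#' Pairwise synteny map between two PULs
#'
#' Matches genes of a reference PUL to genes of a target PUL by reciprocal
#' best sequence-search hits at `e_value <= e_max` (ties broken by lower
#' e-value then lexicographic subject id). Conservation is the fraction of
#' reference genes matched; the order score is the fraction of matched
#' pairs lying on a longest common subsequence of the target gene order
#' taken in reference order.
#'
#' @param pulA Reference `pul` (or character vector of its gene ids, in
#'   order).
#' @param pulB Target `pul` (or ordered gene id vector).
#' @param hitsAB Search hits with queries from A and subjects from B.
#' @param hitsBA Search hits with queries from B and subjects from A.
#' @param e_max E-value threshold (default `1e-5`).
#' @return A list of class `synteny_map`: `pairs` (data frame `ref_gene`,
#'   `target_gene`), `conservation`, `order_score`.
#' @export
synteny_map <- function(pulA, pulB, hitsAB, hitsBA, e_max = 1e-5) {
  idsA <- if (is.character(pulA)) pulA else pulA$gene_ids
  idsB <- if (is.character(pulB)) pulB else pulB$gene_ids
  check_columns(hitsAB, c("query_id", "subject_id", "e_value"),
                "search hit table A->B")
  check_columns(hitsBA, c("query_id", "subject_id", "e_value"),
                "search hit table B->A")

  best <- function(hits, qs, ss) {
    h <- hits[hits$query_id %in% qs & hits$subject_id %in% ss &
                hits$e_value <= e_max, , drop = FALSE]
    if (!nrow(h)) return(character(0))
    h <- h[order_stable(h$query_id, h$e_value, h$subject_id), , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
    setNames(h$subject_id, h$query_id)
  }
  ab <- best(hitsAB, idsA, idsB)
  ba <- best(hitsBA, idsB, idsA)

  ref_gene <- intersect(idsA, names(ab))
  ref_gene <- ref_gene[!is.na(ba[ab[ref_gene]]) & ba[ab[ref_gene]] == ref_gene]
  pairs <- data.frame(ref_gene = ref_gene,
                      target_gene = unname(ab[ref_gene]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(match(pairs$ref_gene, idsA)), , drop = FALSE]
  rownames(pairs) <- NULL

  conservation <- if (length(idsA)) nrow(pairs) / length(idsA) else 0
  order_score <- if (nrow(pairs)) {
    lis_length(match(pairs$target_gene, idsB)) / nrow(pairs)
  } else 0
  structure(list(pairs = pairs, conservation = conservation,
                 order_score = order_score),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat(sprintf("<synteny_map> %d matched pair(s); conservation %.3f; order score %.3f\n",
              nrow(x$pairs), x$conservation, x$order_score))
  invisible(x)
}
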