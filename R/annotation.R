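#' Domain-hit filtering rules
#'
#' Defaults reproduce the documented behaviour of the dbCAN hmmscan parser:
#' an e-value below `1e-5` is required for alignments longer than 80
#' residues and below `1e-3` otherwise, profile coverage must exceed 0.30,
#' and hits on the same protein overlapping more than half of the shorter
#' envelope are resolved by keeping the lower e-value.
#'
#' @param e_long,e_short E-value cutoffs for long / short alignments.
#' @param long_aln Alignment length (residues) above which `e_long` applies.
#' @param min_coverage Minimum profile coverage (exclusive).
#' @param max_overlap Maximum tolerated envelope overlap as a fraction of
#'   the shorter envelope (exclusive; larger overlaps trigger resolution).
#' @return A list of class `annotation_rules`.
#' @export
annotation_rules <- function(e_long = 1e-5, e_short = 1e-3, long_aln = 80L,
                             min_coverage = 0.30, max_overlap = 0.5) {
  stopifnot(e_long > 0, e_short > 0, long_aln >= 0,
            min_coverage >= 0, min_coverage <= 1,
            max_overlap >= 0, max_overlap <= 1)
  structure(list(e_long = e_long, e_short = e_short, long_aln = long_aln,
                 min_coverage = min_coverage, max_overlap = max_overlap),
            class = "annotation_rules")
}

#' Sequence-search confirmation rules
#'
#' Thresholds for confirming an HMM-derived CAZy family call with protein
#' sequence search evidence. All boundaries are inclusive: a hit at exactly
#' the threshold passes ("threshold of E-20" is read as `<= 1e-20`,
#' "minimum" and "at least" as `>=`).
#'
#' @param max_evalue Maximum search e-value.
#' @param min_qcov Minimum query coverage (percent).
#' @param min_pid Minimum percent sequence identity.
#' @param scope `"family"` requires the confirming hit to carry the same
#'   family label as the call; `"protein"` accepts any qualifying hit for
#'   the protein.
#' @return A list of class `confirm_rules`.
#' @export
confirm_rules <- function(max_evalue = 1e-20, min_qcov = 40, min_pid = 30,
                          scope = c("family", "protein")) {
  scope <- match.arg(scope)
  stopifnot(max_evalue > 0, min_qcov >= 0, min_qcov <= 100,
            min_pid >= 0, min_pid <= 100)
  structure(list(max_evalue = max_evalue, min_qcov = min_qcov,
                 min_pid = min_pid, scope = scope),
            class = "confirm_rules")
}

domain_hit_cols <- c("protein_id", "profile_name", "e_value",
                     "alignment_length", "profile_coverage",
                     "env_from", "env_to")
search_hit_cols <- c("query_id", "subject_id", "subject_family",
                     "percent_identity", "query_coverage", "e_value")

validate_domain_hits <- function(hits) {
  check_columns(hits, domain_hit_cols, "domain hit table")
  bad <- !is.finite(hits$e_value) | hits$e_value <= 0 |
    !is.finite(hits$profile_coverage) | hits$profile_coverage < 0 |
    hits$profile_coverage > 1 |
    !is.finite(hits$alignment_length) | hits$alignment_length <= 0 |
    !is.finite(hits$env_from) | !is.finite(hits$env_to) |
    hits$env_from > hits$env_to |
    is.na(hits$protein_id) | is.na(hits$profile_name)
  if (any(bad)) {
    stop(sprintf("malformed domain hit row(s): %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(hits)
}

# strip dbCAN ".hmm" suffixes and Pfam/TIGR version suffixes
clean_profile <- function(x) {
  x <- sub("\\.hmm$", "", x)
  sub("\\.\\d+$", "", x)
}

#' Filter HMM domain hits by dbCAN-parser rules
#'
#' Resolves overlapping hits on one protein (overlap greater than
#' `max_overlap` of the shorter envelope keeps the lower e-value; ties are
#' broken by higher coverage, then profile name), then applies the
#' e-value/alignment-length and coverage thresholds. The operation is
#' idempotent.
#'
#' @param hits Data frame with columns `protein_id`, `profile_name`,
#'   `e_value`, `alignment_length`, `profile_coverage`, `env_from`,
#'   `env_to`.
#' @param rules An [annotation_rules()] object.
#' @return The retained rows, ordered by protein and envelope start.
#' @export
#' @examples
#' h <- data.frame(protein_id = "p1", profile_name = "GH26", e_value = 1e-6,
#'                 alignment_length = 120, profile_coverage = 0.5,
#'                 env_from = 1, env_to = 120)
#' filter_domain_hits(h)
filter_domain_hits <- function(hits, rules = annotation_rules()) {
  stopifnot(inherits(rules, "annotation_rules"))
  validate_domain_hits(hits)
  if (!nrow(hits)) return(hits)

  keep <- logical(nrow(hits))
  for (pid in unique(hits$protein_id)) {
    rows <- which(hits$protein_id == pid)
    h <- hits[rows, , drop = FALSE]
    ord <- order_stable(h$e_value, -h$profile_coverage, h$profile_name,
                        h$env_from)
    taken <- integer(0)
    for (i in ord) {
      s <- h$env_from[i]; e <- h$env_to[i]; len <- e - s + 1
      clash <- FALSE
      for (j in taken) {
        ov <- min(e, h$env_to[j]) - max(s, h$env_from[j]) + 1
        if (ov > 0) {
          shorter <- min(len, h$env_to[j] - h$env_from[j] + 1)
          if (ov / shorter > rules$max_overlap) { clash <- TRUE; break }
        }
      }
      if (!clash) taken <- c(taken, i)
    }
    keep[rows[taken]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]

  e_cut <- ifelse(out$alignment_length > rules$long_aln,
                  rules$e_long, rules$e_short)
  pass <- out$e_value < e_cut & out$profile_coverage > rules$min_coverage
  out <- out[pass, , drop = FALSE]
  out <- out[order_stable(out$protein_id, out$env_from, out$profile_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

sus_profile_map <- function() {
  c(TIGR04056 = "SUSC",
    PF12741 = "SUSD", PF12771 = "SUSD", PF14322 = "SUSD", PF07980 = "SUSD")
}

#' Classify SusC / SusD proteins from filtered domain hits
#'
#' `TIGR04056` maps to `SUSC`; the SusD-like Pfam profiles `PF12741`,
#' `PF12771`, `PF14322` and `PF07980` (version suffixes ignored) map to
#' `SUSD`. A protein hitting both profile classes is flagged as a conflict
#' and resolved by the lower e-value. Profiles outside this set are ignored
#' with a message.
#'
#' @param hits Filtered domain hits (see [filter_domain_hits()]).
#' @param quiet Suppress the message about ignored profiles.
#' @return Data frame with `protein_id`, `label`, `family`, `evidence`,
#'   `e_value`, `conflict`.
#' @export
classify_sus <- function(hits, quiet = FALSE) {
  check_columns(hits, c("protein_id", "profile_name", "e_value"),
                "domain hit table")
  map <- sus_profile_map()
  base <- clean_profile(hits$profile_name)
  lab <- unname(map[base])
  unknown <- is.na(lab)
  if (any(unknown) && !quiet) {
    message(sprintf("classify_sus: ignoring %d hit(s) on unrecognized profile(s): %s",
                    sum(unknown),
                    paste(unique(base[unknown]), collapse = ", ")))
  }
  h <- hits[!unknown, , drop = FALSE]
  lab <- lab[!unknown]
  if (!nrow(h)) {
    return(data.frame(protein_id = character(0), label = character(0),
                      family = character(0), evidence = character(0),
                      e_value = numeric(0), conflict = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(seq_len(nrow(h)), h$protein_id), function(rows) {
    conflict <- length(unique(lab[rows])) > 1L
    best <- rows[order_stable(h$e_value[rows], lab[rows])][1L]
    data.frame(protein_id = h$protein_id[best], label = lab[best],
               family = lab[best], evidence = "HMM",
               e_value = h$e_value[best], conflict = conflict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order_stable(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

cazy_family_pattern <- "^(GH|GT|PL|CE|CBM|AA)\\d"

# CAZy family calls (one per protein x family, best e-value) from filtered hits
cazy_calls <- function(hits) {
  fam <- clean_profile(hits$profile_name)
  sel <- grepl(cazy_family_pattern, fam)
  h <- hits[sel, , drop = FALSE]
  fam <- fam[sel]
  if (!nrow(h)) {
    return(data.frame(protein_id = character(0), label = character(0),
                      family = character(0), evidence = character(0),
                      e_value = numeric(0), conflict = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(h$protein_id, fam, sep = "\r")
  best <- vapply(split(seq_len(nrow(h)), key),
                 function(rows) rows[which.min(h$e_value[rows])], integer(1))
  out <- data.frame(protein_id = h$protein_id[best], label = fam[best],
                    family = fam[best], evidence = "HMM",
                    e_value = h$e_value[best], conflict = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order_stable(out$protein_id, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relabel glycosyl transferase calls
#'
#' Calls whose family begins with `GT` receive the label `GT`; downstream
#' genetic-context scans never count them as CAZymes. The original family
#' string is kept in the `family` column.
#'
#' @param calls Annotation call data frame (columns `label`, `family`).
#' @return The calls with GT families relabeled.
#' @export
label_gt <- function(calls) {
  check_columns(calls, c("label", "family"), "annotation calls")
  gt <- grepl("^GT", calls$family) & !(calls$label %in% c("SUSC", "SUSD"))
  calls$label[gt] <- "GT"
  calls
}

#' Confirm CAZy family calls with sequence-search evidence
#'
#' A CAZy family call survives confirmed mode iff some search hit for the
#' protein passes all three thresholds of `rules` (inclusive boundaries)
#' and -- under the default `"family"` scope -- carries the same family
#' label. `SUSC`, `SUSD` and `GT` calls pass through unchanged. In
#' `"hmm_only"` mode confirmation is bypassed entirely.
#'
#' @param calls Annotation calls (from the HMM stage).
#' @param search_hits Data frame with columns `query_id`, `subject_id`,
#'   `subject_family`, `percent_identity`, `query_coverage`, `e_value`.
#' @param rules A [confirm_rules()] object.
#' @param mode `"confirmed"` (default) or `"hmm_only"`.
#' @return The retained calls; confirmed CAZy calls have evidence
#'   `"HMM+SEARCH"`.
#' @export
confirm_calls <- function(calls, search_hits = NULL,
                          rules = confirm_rules(),
                          mode = c("confirmed", "hmm_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rules, "confirm_rules"))
  check_columns(calls, c("protein_id", "label", "family", "evidence"),
                "annotation calls")
  if (mode == "hmm_only") return(calls)
  if (is.null(search_hits)) {
    stop("confirmed mode requires a search hit table (or use mode = \"hmm_only\")",
         call. = FALSE)
  }
  check_columns(search_hits, search_hit_cols, "search hit table")

  exempt <- calls$label %in% c("SUSC", "SUSD", "GT")
  need <- which(!exempt)
  if (!length(need)) return(calls)

  ok_hit <- search_hits$e_value <= rules$max_evalue &
    search_hits$query_coverage >= rules$min_qcov &
    search_hits$percent_identity >= rules$min_pid
  sh <- search_hits[ok_hit, , drop = FALSE]
  confirmed <- if (rules$scope == "family") {
    paste(calls$protein_id[need], calls$family[need], sep = "\r") %in%
      paste(sh$query_id, sh$subject_family, sep = "\r")
  } else {
    calls$protein_id[need] %in% sh$query_id
  }
  calls$evidence[need[confirmed]] <- "HMM+SEARCH"
  keep <- rep(TRUE, nrow(calls))
  keep[need[!confirmed]] <- FALSE
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a genome from domain and search hit tables
#'
#' Composes the full dual-evidence annotation: dbCAN-style domain hit
#' filtering, SusC/D classification, CAZy family calling, GT relabeling and
#' (in confirmed mode) sequence-search confirmation. The result is a total
#' map over genes: genes without any retained call simply have no rows.
#'
#' @param genes Gene table (column `gene_id`; protein ids in the hit tables
#'   must resolve to gene ids).
#' @param domain_hits,search_hits Hit tables; see [filter_domain_hits()]
#'   and [confirm_calls()].
#' @param mode `"confirmed"` (default) or `"hmm_only"`.
#' @param rules An [annotation_rules()] object.
#' @param confirm A [confirm_rules()] object.
#' @param quiet Passed to [classify_sus()].
#' @return Data frame of class `annotation_calls` with columns
#'   `gene_id`, `label`, `family`, `evidence`, `e_value`, `conflict`.
#' @export
annotate_genome <- function(genes, domain_hits, search_hits = NULL,
                            mode = c("confirmed", "hmm_only"),
                            rules = annotation_rules(),
                            confirm = confirm_rules(), quiet = TRUE) {
  mode <- match.arg(mode)
  check_columns(genes, "gene_id", "gene table")
  validate_domain_hits(domain_hits)

  bad <- setdiff(unique(domain_hits$protein_id), genes$gene_id)
  if (!is.null(search_hits)) {
    check_columns(search_hits, search_hit_cols, "search hit table")
    bad <- union(bad, setdiff(unique(search_hits$query_id), genes$gene_id))
  }
  if (length(bad)) {
    stop(sprintf("hit table protein id(s) do not resolve to gene ids: %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }

  filtered <- filter_domain_hits(domain_hits, rules)
  is_sus <- clean_profile(filtered$profile_name) %in% names(sus_profile_map())
  sus <- classify_sus(filtered[is_sus, , drop = FALSE], quiet = quiet)
  caz <- cazy_calls(filtered[!is_sus, , drop = FALSE])
  calls <- rbind(sus, caz)
  calls <- label_gt(calls)
  calls <- confirm_calls(calls, search_hits, confirm, mode)

  names(calls)[names(calls) == "protein_id"] <- "gene_id"
  ord <- order_stable(match(calls$gene_id, genes$gene_id), calls$family)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("annotation_calls", "data.frame")
  attr(calls, "gene_ids") <- genes$gene_id
  calls
}

#' Labels assigned to one gene
#'
#' @param annotations An `annotation_calls` data frame.
#' @param gene_id Gene identifier.
#' @return Character vector of labels (empty if the gene has no call).
#' @export
gene_labels <- function(annotations, gene_id) {
  annotations$label[annotations$gene_id == gene_id]
}
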