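# Readers and writers for the exchange formats used around the pipeline:
# flat gene tables, GFF3, HMMER3 domain tables, BLAST tabular search hits,
# intensity / spot TSVs and truth JSON.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write a flat gene table
#'
#' Tab-separated table with columns `gene_id`, `contig_id`, `order_index`,
#' `start`, `end`, `strand` and optionally `locus_tag`.
#'
#' @param genes Gene table data frame.
#' @param path File path.
#' @return `read_gene_table` returns the gene table; `write_gene_table`
#'   returns `path` invisibly.
#' @export
write_gene_table <- function(genes, path) {
  validate_genes(genes)
  write_tsv(genes, path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  validate_genes(g)
  g
}

#' Read / write gene models as GFF3
#'
#' Genes are exported as `gene` features with `ID` and `locus_tag`
#' attributes; order along each contig is recovered from coordinates on
#' import.
#'
#' @param genes Gene table data frame.
#' @param path File path.
#' @return `read_genes_gff3` returns a gene table; `write_genes_gff3`
#'   returns `path` invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  validate_genes(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$locus_tag <-
    if ("locus_tag" %in% names(genes)) genes$locus_tag else genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  df <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_tag = S4Vectors::mcols(gr)$locus_tag %||%
      S4Vectors::mcols(gr)$ID,
    stringsAsFactors = FALSE)
  df <- df[order_stable(df$contig_id, df$start), , drop = FALSE]
  df$order_index <- unlist(lapply(split(seq_len(nrow(df)), df$contig_id),
                                  seq_along), use.names = FALSE) - 1L
  df <- df[, c("gene_id", "contig_id", "order_index", "start", "end",
               "strand", "locus_tag")]
  rownames(df) <- NULL
  validate_genes(df)
  df
}

#' Write placeholder protein sequences for a gene table
#'
#' Emits one record per gene with a synthetic (deterministic, seeded)
#' amino-acid sequence. The sequences carry no biological signal; they only
#' give downstream tools that insist on FASTA input something well-formed
#' to chew on.
#'
#' @param genes Gene table data frame.
#' @param path Output FASTA path.
#' @param seed Seed for the synthetic residues.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genes, path, seed = 1L) {
  validate_genes(genes)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- with_seed(seed, vapply(seq_len(nrow(genes)), function(i) {
    paste0("M", paste(sample(aas, 120, replace = TRUE), collapse = ""))
  }, character(1)))
  x <- Biostrings::AAStringSet(setNames(seqs, genes$gene_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# HMMER3 domain table (domtblout dialect): whitespace-delimited, '#'
# comments, 22 fixed columns plus free-text description. Profile length is
# written as 1000 so that hmm coordinates encode the profile coverage.
domtbl_header <- c(
  "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
  "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target")

#' Read / write HMM domain hits in HMMER3 domain-table dialect
#'
#' The writer produces a `hmmscan --domtblout`-style table (profiles as
#' targets, proteins as queries); the reader recovers `protein_id`,
#' `profile_name`, `e_value` (domain independent e-value),
#' `alignment_length` (ali coordinates) and `profile_coverage` (hmm
#' coordinates over the profile length).
#'
#' @param hits Domain hit data frame (see [filter_domain_hits()]).
#' @param path File path.
#' @return `read_domain_hits` returns the hit data frame;
#'   `write_domain_hits` returns `path` invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  validate_domain_hits(hits)
  tlen <- 1000L
  hmm_to <- pmax(1L, round(hits$profile_coverage * tlen))
  lines <- sprintf(
    "%-20s %-11s %4d %-20s %-11s %4d %9.1e %6.1f %5.1f %3d %3d %9.1e %9.3e %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    paste0(hits$profile_name, ".hmm"), "-", tlen,
    hits$protein_id, "-", hits$env_to + 50L,
    hits$e_value, 100, 0.1, 1L, 1L, hits$e_value, hits$e_value, 95, 0.1,
    1L, hmm_to,
    hits$env_from, hits$env_from + hits$alignment_length - 1L,
    hits$env_from, hits$env_to, 0.9, "-")
  writeLines(c(domtbl_header, lines, "#"), path)
  invisible(path)
}

#' @rdname write_domain_hits
#' @export
read_domain_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(protein_id = character(0), profile_name = character(0),
                      e_value = numeric(0), alignment_length = numeric(0),
                      profile_coverage = numeric(0), env_from = integer(0),
                      env_to = integer(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(lines), "[[:space:]]+")
  num <- function(i) vapply(f, function(x) as.numeric(x[i]), numeric(1))
  chr <- function(i) vapply(f, function(x) x[i], character(1))
  data.frame(
    protein_id = chr(4),
    profile_name = sub("\\.hmm$", "", chr(1)),
    e_value = num(13),
    alignment_length = as.integer(num(19) - num(18) + 1),
    profile_coverage = (num(17) - num(16) + 1) / num(3),
    env_from = as.integer(num(20)),
    env_to = as.integer(num(21)),
    stringsAsFactors = FALSE)
}

#' Read / write search hits in BLAST tabular dialect
#'
#' Columns are the standard 12 (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`) extended with
#' `qcovs` (query coverage) and `sfamily` (CAZy family of the subject),
#' matching a `-outfmt "6 std qcovs"` run against a family-tagged database.
#'
#' @param hits Search hit data frame (see [confirm_calls()]).
#' @param path File path.
#' @return `read_search_hits` returns the hit data frame;
#'   `write_search_hits` returns `path` invisibly.
#' @export
write_search_hits <- function(hits, path) {
  check_columns(hits, search_hit_cols, "search hit table")
  aln <- 200L
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$percent_identity, 3), length = aln,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = aln,
    sstart = 1L, send = aln,
    evalue = formatC(hits$e_value, format = "e", digits = 3),
    bitscore = 500,
    qcovs = round(hits$query_coverage, 3),
    sfamily = hits$subject_family,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_search_hits
#' @export
read_search_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qcovs", "sfamily")
  df <- read.delim(path, header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  data.frame(query_id = df$qseqid, subject_id = df$sseqid,
             subject_family = df$sfamily, percent_identity = df$pident,
             query_coverage = df$qcovs, e_value = df$evalue,
             stringsAsFactors = FALSE)
}

#' Read / write an intensity matrix with its sample metadata sidecar
#'
#' The matrix is stored as a TSV with a `protein_id` first column; the
#' sidecar (same path with extension `.samples.tsv`) holds `sample_id`,
#' `condition`, `replicate`.
#'
#' @param mat Proteins x samples matrix.
#' @param metadata Sample metadata data frame.
#' @param path Matrix file path.
#' @return `read_intensity_matrix` returns `list(intensities, metadata)`;
#'   `write_intensity_matrix` returns `path` invisibly.
#' @export
write_intensity_matrix <- function(mat, metadata, path) {
  mat <- as_intensity_matrix(mat)
  metadata <- check_metadata(mat, metadata)
  df <- data.frame(protein_id = rownames(mat) %||%
                     as.character(seq_len(nrow(mat))),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(metadata, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("(\\.[^.]+)?$", ".samples.tsv",
                                   path)

#' @rdname write_intensity_matrix
#' @export
read_intensity_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  metadata <- read.delim(sidecar_path(path), stringsAsFactors = FALSE)
  list(intensities = m, metadata = check_metadata(m, metadata))
}

#' Read / write microarray spot tables
#'
#' @param spots Spot table data frame (see [mean_replicates()]).
#' @param path File path.
#' @return `read_spot_table` returns the spot table; `write_spot_table`
#'   returns `path` invisibly.
#' @export
write_spot_table <- function(spots, path) {
  check_columns(spots, spot_cols, "spot table")
  write_tsv(spots, path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(s, spot_cols, "spot table")
  s
}

#' Write ground truth as JSON
#'
#' @param truth A `genome_truth` object or any list of plain data.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
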