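# Readers, writers and filters for every tabular input: phenotype-gene
# associations, term mappings, symptom-cluster records, scored interactome
# edges, drug-target pairs, GMT gene-set collections and category
# annotations. All text IO is UTF-8; clinical terms may be non-ASCII.

#' Construct an association table
#'
#' A bipartite phenotype-gene association set with per-entity indexes. The
#' canonical container behind the curated symptom-gene (or disease-gene)
#' association inputs.
#'
#' @param records data frame with columns `phenotype_id`, `phenotype_label`,
#'   `gene` (and optionally `semantic_type`). Duplicate
#'   (phenotype_id, gene) pairs are collapsed, keeping the first label.
#' @return An object of class `assoc_table`: list with `records` (the
#'   deduplicated data frame), `index` (phenotype_id -> character vector of
#'   genes) and `reverse_index` (gene -> character vector of phenotype_ids).
#' @export
association_table <- function(records) {
  require_columns(records, c("phenotype_id", "phenotype_label", "gene"),
                  "association table")
  records$phenotype_id <- as.character(records$phenotype_id)
  records$gene <- as.character(records$gene)
  if (any(!nzchar(records$phenotype_id)) || any(!nzchar(records$gene))) {
    stop("association table: empty phenotype_id or gene", call. = FALSE)
  }
  records <- records[!duplicated(records[, c("phenotype_id", "gene")]), ,
                     drop = FALSE]
  rownames(records) <- NULL
  index <- lapply(split(records$gene, records$phenotype_id), unique)
  reverse_index <- lapply(split(records$phenotype_id, records$gene), unique)
  structure(list(records = records, index = index,
                 reverse_index = reverse_index),
            class = "assoc_table")
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf(
    "Phenotype-gene association table: %d associations, %d phenotypes, %d genes\n",
    nrow(x$records), length(x$index), length(x$reverse_index)))
  invisible(x)
}

#' Read a phenotype-gene association table
#'
#' Reads a TSV with at least `phenotype_id`, `phenotype_label` and `gene`
#' columns, optionally filters rows by UMLS-style semantic type (the curated
#' input restricts concepts to the sign-or-symptom type `T184`), removes
#' phenotypes on a drop list (the stand-in for a manual review), and
#' deduplicates (phenotype, gene) pairs. The semantic-type filter is
#' row-wise.
#'
#' @param path TSV path (gzip accepted).
#' @param semantic_type_filter optional semantic-type code; only matching
#'   rows survive (requires a `semantic_type` column).
#' @param drop_list optional character vector of phenotype_ids or labels to
#'   remove entirely.
#' @return An [association_table()].
#' @export
read_associations <- function(path, semantic_type_filter = NULL,
                              drop_list = NULL) {
  df <- read_tsv(path)
  require_columns(df, c("phenotype_id", "phenotype_label", "gene"),
                  "read_associations")
  n0 <- nrow(df)
  if (!is.null(semantic_type_filter)) {
    require_columns(df, "semantic_type", "read_associations (semantic filter)")
    df <- df[df$semantic_type %in% semantic_type_filter, , drop = FALSE]
    message(sprintf("read_associations: semantic-type filter removed %d/%d rows",
                    n0 - nrow(df), n0))
  }
  if (!is.null(drop_list) && length(drop_list)) {
    keep <- !(df$phenotype_id %in% drop_list |
                df$phenotype_label %in% drop_list)
    message(sprintf("read_associations: drop list removed %d rows",
                    sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (!nrow(df)) {
    warning("read_associations: no records survived filtering (empty table)",
            call. = FALSE)
    df <- df[, c("phenotype_id", "phenotype_label", "gene"), drop = FALSE]
  }
  association_table(df)
}

#' Read a term-mapping table
#'
#' Many-to-one mapping from source phenotype identifiers (e.g., CUI codes)
#' to merged clinical terms; several codes may map to one term, each code
#' appears at most once.
#'
#' @param path TSV with columns `source` and `target`.
#' @return named character vector: `names()` are sources, values targets.
#' @export
read_term_mapping <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("source", "target"), "read_term_mapping")
  if (anyDuplicated(df$source)) {
    stop("read_term_mapping: duplicated source identifiers", call. = FALSE)
  }
  setNames(as.character(df$target), as.character(df$source))
}

#' Merge association phenotypes through a term mapping
#'
#' Phenotype identifiers sharing a mapped clinical term are merged; the
#' merged gene set is the union of the constituents' sets. Phenotypes
#' without a mapping entry have no clinical-term counterpart and are
#' dropped (their count is reported); mapping sources absent from the table
#' are ignored with a log line.
#'
#' @param assoc an [association_table()].
#' @param mapping named character vector as returned by
#'   [read_term_mapping()].
#' @return An [association_table()] keyed by clinical term (the merged term
#'   becomes both `phenotype_id` and `phenotype_label`).
#' @export
apply_term_mapping <- function(assoc, mapping) {
  stopifnot(inherits(assoc, "assoc_table"))
  rec <- assoc$records
  unused <- setdiff(names(mapping), rec$phenotype_id)
  if (length(unused)) {
    message(sprintf("apply_term_mapping: %d mapping source(s) not present in table",
                    length(unused)))
  }
  mapped <- rec$phenotype_id %in% names(mapping)
  n_drop <- length(unique(rec$phenotype_id[!mapped]))
  if (n_drop) {
    message(sprintf("apply_term_mapping: dropped %d unmapped phenotype(s)",
                    n_drop))
  }
  rec <- rec[mapped, , drop = FALSE]
  if (!nrow(rec)) {
    warning("apply_term_mapping: no mapped phenotypes remain", call. = FALSE)
  }
  term <- unname(mapping[rec$phenotype_id])
  association_table(data.frame(phenotype_id = term, phenotype_label = term,
                               gene = rec$gene, stringsAsFactors = FALSE))
}

#' Read a scored interactome edge list
#'
#' STRING-style TSV with two protein columns and an integer combined score
#' in 0-1000. Edges at or above the threshold are kept (the curated network
#' uses score >= 700), self-pairs are removed and reversed duplicates are
#' collapsed to one undirected edge.
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `score`.
#' @param score_threshold inclusive minimum score (default 700).
#' @return data frame `protein_a`, `protein_b`, `score` with
#'   `protein_a < protein_b` per row; class `interactome_edges`.
#' @export
read_interactome <- function(path, score_threshold = 700) {
  df <- read_tsv(path)
  require_columns(df, c("protein_a", "protein_b", "score"), "read_interactome")
  score_num <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score_num) || any(score_num != floor(score_num))) {
    stop("read_interactome: scores must be integers", call. = FALSE)
  }
  if (any(score_num < 0 | score_num > 1000)) {
    stop("read_interactome: scores outside 0-1000", call. = FALSE)
  }
  df$score <- as.integer(score_num)
  df <- df[df$score >= score_threshold, , drop = FALSE]
  a <- as.character(df$protein_a)
  b <- as.character(df$protein_b)
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  out <- data.frame(protein_a = lo, protein_b = hi,
                    score = df$score[keep], stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("protein_a", "protein_b")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interactome_edges", "data.frame")
  out
}

#' Summarize an association table
#'
#' Counts plus the two marginal means: genes per phenotype and phenotypes
#' per gene, each reported both at full precision and rounded half-up to 2
#' decimals, together with the two degree histograms.
#'
#' @param assoc an [association_table()].
#' @return list with `n_phenotypes`, `n_genes`, `n_associations`,
#'   `mean_genes_per_phenotype`, `mean_phenotypes_per_gene` (full
#'   precision), `*_rounded` variants, and `genes_per_phenotype` /
#'   `phenotypes_per_gene` count tables.
#' @export
summarize_associations <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_table"))
  if (!nrow(assoc$records)) {
    stop("summarize_associations: empty association table", call. = FALSE)
  }
  gpp <- lengths(assoc$index)
  ppg <- lengths(assoc$reverse_index)
  n_assoc <- nrow(assoc$records)
  list(
    n_phenotypes = length(gpp),
    n_genes = length(ppg),
    n_associations = n_assoc,
    mean_genes_per_phenotype = n_assoc / length(gpp),
    mean_phenotypes_per_gene = n_assoc / length(ppg),
    mean_genes_per_phenotype_rounded = round_half_up(n_assoc / length(gpp)),
    mean_phenotypes_per_gene_rounded = round_half_up(n_assoc / length(ppg)),
    genes_per_phenotype = table(gpp),
    phenotypes_per_gene = table(ppg)
  )
}

#' Read symptom-cluster records
#'
#' One record per line, tab-separated symptom terms. With
#' `chief_column = TRUE` (the default) the first field is the record's
#' chief symptom and the remaining fields its accompanying cluster.
#' Within-record duplicate terms are collapsed.
#'
#' @param path text file path (gzip accepted).
#' @param chief_column whether the first field is the chief symptom.
#' @return object of class `cluster_records`: list with `records` (list of
#'   character vectors of accompanying terms) and `chief` (character vector
#'   or NULL).
#' @export
read_cluster_records <- function(path, chief_column = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) unique(f[nzchar(f)]))
  empty <- !lengths(fields)
  if (any(empty)) fields <- fields[!empty]
  if (!length(fields)) stop("read_cluster_records: no records", call. = FALSE)
  if (chief_column) {
    chief <- vapply(fields, `[[`, "", 1L)
    records <- lapply(fields, function(f) f[-1L])
  } else {
    chief <- NULL
    records <- fields
  }
  cluster_records(records, chief)
}

#' Construct a cluster-record set
#'
#' @param records list of character vectors (accompanying symptom terms).
#' @param chief optional chief-symptom term per record.
#' @return object of class `cluster_records`.
#' @export
cluster_records <- function(records, chief = NULL) {
  records <- lapply(records, function(r) unique(as.character(r)))
  if (!is.null(chief)) {
    stopifnot(length(chief) == length(records))
    chief <- as.character(chief)
  }
  n_terms <- lengths(records) + if (is.null(chief)) 0L else nzchar(chief)
  if (any(n_terms < 1L)) {
    stop("cluster_records: every record needs at least one term", call. = FALSE)
  }
  structure(list(records = records, chief = chief), class = "cluster_records")
}

#' @export
print.cluster_records <- function(x, ...) {
  cat(sprintf("Symptom cluster records: %d records, %d distinct terms%s\n",
              length(x$records),
              length(unique(c(unlist(x$records), x$chief))),
              if (is.null(x$chief)) "" else " (with chief symptoms)"))
  invisible(x)
}

#' Write cluster records
#' @param records a [cluster_records()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_records <- function(records, path) {
  stopifnot(inherits(records, "cluster_records"))
  lines <- vapply(seq_along(records$records), function(i) {
    terms <- records$records[[i]]
    if (!is.null(records$chief)) terms <- c(records$chief[i], terms)
    paste(terms, collapse = "\t")
  }, "")
  writeLines(lines, con <- file(path, "w", encoding = "UTF-8"))
  close(con)
  invisible(path)
}

#' Read a drug-target table
#'
#' @param path TSV with columns `drug_id`, `target_gene`.
#' @return deduplicated data frame with those two columns.
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("drug_id", "target_gene"), "read_drug_targets")
  df$drug_id <- as.character(df$drug_id)
  df$target_gene <- as.character(df$target_gene)
  if (any(!nzchar(df$drug_id)) || any(!nzchar(df$target_gene))) {
    stop("read_drug_targets: empty drug_id or target_gene", call. = FALSE)
  }
  df <- df[!duplicated(df[, c("drug_id", "target_gene")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line; tab-separated fields are the set
#' name, a description, then member genes.
#'
#' @param path GMT path (gzip accepted).
#' @return object of class `gene_set_collection`: list with `sets` (name ->
#'   character vector of genes), `descriptions` (name -> description) and
#'   `universe` (union of all member genes).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("read_gene_sets: GMT lines need name, description and >= 1 gene",
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("read_gene_sets: duplicated set names",
                              call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (each non-empty).
#' @param descriptions optional descriptions (recycled "" if absent).
#' @param universe optional gene universe; defaults to the union of sets.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (any(!lengths(sets))) {
    stop("gene_set_collection: empty gene set", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe %||% unique(unlist(sets, use.names = FALSE))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets, %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, con <- file(path, "w", encoding = "UTF-8"))
  close(con)
  invisible(path)
}

#' Read a term-to-category annotation
#'
#' Maps each symptom term to exactly one body-system category (e.g., the 14
#' symptom-ontology systems).
#'
#' @param path TSV with columns `term`, `category`.
#' @return named character vector term -> category.
#' @export
read_category_annotation <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("term", "category"), "read_category_annotation")
  if (anyDuplicated(df$term)) {
    stop("read_category_annotation: a term maps to more than one category",
         call. = FALSE)
  }
  setNames(as.character(df$category), as.character(df$term))
}

#' Write an association table as TSV
#' @param assoc an [association_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_table"))
  write_tsv(assoc$records, path)
}
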