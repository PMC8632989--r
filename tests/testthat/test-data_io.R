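test_that("association reading deduplicates, filters by semantic type and drop list", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    phenotype_id = c("C1", "C1", "C1", "C2", "C2"),
    phenotype_label = "x",
    gene = c("A", "A", "B", "A", "A"),
    semantic_type = c("T184", "T184", "T184", "T184", "T184"))
  write_tsv(df, tmp)
  at <- read_associations(tmp)
  expect_equal(nrow(at$records), 3L)   # 5 rows, 2 duplicated pairs

  df$semantic_type <- c("T184", "T047", "T184", "T047", "T184")
  write_tsv(df, tmp)
  at <- suppressMessages(read_associations(tmp, semantic_type_filter = "T184"))
  expect_true(all(at$records$phenotype_id %in% c("C1", "C2")))
  expect_equal(nrow(at$records), 3L)   # only T184 rows survive, then dedup

  # drop-list recount oracle on a 100-row random fixture
  set.seed(31)
  big <- rand_assoc_df(25, 40)
  big <- big[sample.int(nrow(big), min(100, nrow(big))), ]
  big$semantic_type <- "T184"
  drop <- sprintf("p%02d", 1:10)
  write_tsv(big, tmp)
  at <- suppressMessages(read_associations(tmp, drop_list = drop))
  # independent line-by-line recount over the raw file
  raw <- read.delim(tmp, sep = "\t", stringsAsFactors = FALSE)
  keep <- !(raw$phenotype_id %in% drop)
  expected <- sum(!duplicated(raw[keep, c("phenotype_id", "gene")]))
  expect_equal(nrow(at$records), expected)
})

test_that("association table enforces its index invariants", {
  set.seed(5)
  at <- association_table(rand_assoc_df(10, 20))
  # index and reverse index are exact inverses
  for (p in names(at$index)) {
    for (g in at$index[[p]]) {
      expect_true(p %in% at$reverse_index[[g]])
    }
  }
  expect_equal(nrow(at$records), sum(lengths(at$index)))
  expect_equal(nrow(at$records), sum(lengths(at$reverse_index)))
  expect_error(association_table(data.frame(phenotype_id = "", gene = "A",
                                            phenotype_label = "x")),
               "empty")
  expect_error(
    read_associations(withr::local_tempfile(lines = "a\tb\nc\td")),
    "missing required column")
})

test_that("term mapping merges gene sets by union and drops unmapped phenotypes", {
  at <- association_table(data.frame(
    phenotype_id = c("C1", "C1", "C2", "C2", "C3"),
    phenotype_label = "x",
    gene = c("A", "B", "B", "C", "D")))
  mapped <- suppressMessages(
    apply_term_mapping(at, c(C1 = "fever", C2 = "fever")))
  expect_setequal(mapped$index[["fever"]], c("A", "B", "C"))
  expect_false("C3" %in% mapped$records$phenotype_id)  # unmapped dropped

  # identity mapping leaves the table unchanged
  ids <- unique(at$records$phenotype_id)
  ident <- suppressMessages(apply_term_mapping(at, setNames(ids, ids)))
  expect_equal(ident$index[ids], at$index[ids])

  # brute-force union oracle on a random 30-id table with a 3-to-1 mapping
  set.seed(11)
  big <- association_table(rand_assoc_df(30, 40))
  src <- sprintf("p%02d", 1:30)
  tgt <- rep(sprintf("term%02d", 1:10), each = 3)
  mapping <- setNames(tgt, src)
  merged <- suppressMessages(apply_term_mapping(big, mapping))
  for (tm in unique(tgt)) {
    expected <- unique(unlist(big$index[src[tgt == tm]]))
    expect_setequal(merged$index[[tm]], expected)
  }
})

test_that("interactome reading applies inclusive threshold, collapses duplicates, rejects bad scores", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_a = c("A", "B", "C"),
                       protein_b = c("B", "C", "D"),
                       score = c(699L, 700L, 701L)), tmp)
  ed <- read_interactome(tmp, 700)
  expect_equal(nrow(ed), 2L)           # >= 700 is inclusive

  write_tsv(data.frame(protein_a = c("A", "B", "A"),
                       protein_b = c("B", "A", "A"),
                       score = c(900L, 900L, 950L)), tmp)
  ed <- read_interactome(tmp, 700)
  expect_equal(nrow(ed), 1L)           # reversed duplicate + self-pair removed
  expect_true(all(ed$protein_a < ed$protein_b))

  write_tsv(data.frame(protein_a = "A", protein_b = "B", score = "high"), tmp)
  expect_error(read_interactome(tmp, 700), "integer")

  # recount oracle on a 500-edge random file
  set.seed(17)
  prot <- sprintf("P%03d", 1:60)
  df <- data.frame(protein_a = sample(prot, 500, TRUE),
                   protein_b = sample(prot, 500, TRUE),
                   score = sample(0:1000, 500, TRUE))
  write_tsv(df, tmp)
  ed <- read_interactome(tmp, 700)
  ok <- df$score >= 700 & df$protein_a != df$protein_b
  key <- paste(pmin(df$protein_a, df$protein_b)[ok],
               pmax(df$protein_a, df$protein_b)[ok])
  expect_equal(nrow(ed), length(unique(key)))
  expect_false(any(duplicated(paste(ed$protein_a, ed$protein_b))))
})

test_that("association summaries satisfy the count identities", {
  at <- association_table(data.frame(phenotype_id = "p", phenotype_label = "p",
                                     gene = "g"))
  s <- summarize_associations(at)
  expect_equal(s$mean_genes_per_phenotype_rounded, 1.00)
  expect_equal(s$mean_phenotypes_per_gene_rounded, 1.00)

  set.seed(3)
  at <- association_table(rand_assoc_df(15, 25))
  s <- summarize_associations(at)
  expect_equal(s$n_associations,
               s$mean_genes_per_phenotype * s$n_phenotypes)
  expect_equal(s$n_associations,
               s$mean_phenotypes_per_gene * s$n_genes)
  expect_equal(sum(as.integer(names(s$genes_per_phenotype)) *
                     as.integer(s$genes_per_phenotype)), s$n_associations)
  expect_error(summarize_associations(
    association_table(data.frame(phenotype_id = character(),
                                 phenotype_label = character(),
                                 gene = character()))), "empty")
})

test_that("half-up rounding differs from banker's rounding where it should", {
  # 0.125 is exactly representable: banker's gives 0.12, half-up 0.13
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(-0.125), -0.13)
  expect_equal(round(0.125, 2), 0.12)
  expect_equal(round_half_up(37.29912, 2), 37.30)
})

test_that("every table type round-trips through its writer and reader", {
  dir <- withr::local_tempdir()

  set.seed(23)
  at <- association_table(rand_assoc_df(12, 20))
  write_associations(at, file.path(dir, "a.tsv"))
  at2 <- read_associations(file.path(dir, "a.tsv"))
  expect_equal(at2$index, at$index)

  # cluster records, including non-ASCII clinical terms
  cr <- cluster_records(list(c("发热", "headache"), "cough"),
                        chief = c("失眠", "fever"))
  write_cluster_records(cr, file.path(dir, "r.tsv"))
  cr2 <- read_cluster_records(file.path(dir, "r.tsv"))
  expect_equal(cr2$records, cr$records)
  expect_equal(cr2$chief, cr$chief)

  gsc <- gene_set_collection(list(s1 = c("A", "B"), s2 = c("B", "C", "D")),
                             c("one", "two"))
  write_gene_sets(gsc, file.path(dir, "g.gmt"))
  gsc2 <- read_gene_sets(file.path(dir, "g.gmt"))
  expect_equal(gsc2$sets, gsc$sets)
  expect_setequal(gsc2$universe, c("A", "B", "C", "D"))

  dt <- data.frame(drug_id = c("D1", "D1", "D2"),
                   target_gene = c("A", "B", "A"), stringsAsFactors = FALSE)
  write_tsv(dt, file.path(dir, "d.tsv"))
  expect_equal(read_drug_targets(file.path(dir, "d.tsv")), dt)

  mp <- c(C1 = "fever", C2 = "fever", C3 = "cough")
  write_tsv(data.frame(source = names(mp), target = unname(mp)),
            file.path(dir, "m.tsv"))
  expect_equal(read_term_mapping(file.path(dir, "m.tsv")), mp)

  ann <- c(fever = "SYS01", cough = "SYS02")
  write_tsv(data.frame(term = names(ann), category = unname(ann)),
            file.path(dir, "c.tsv"))
  expect_equal(read_category_annotation(file.path(dir, "c.tsv")), ann)

  # gzip transparently accepted
  gz <- file.path(dir, "a.tsv.gz")
  con <- gzfile(gz, "w"); writeLines(readLines(file.path(dir, "a.tsv")), con)
  close(con)
  expect_equal(read_associations(gz)$index, at$index)
})
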