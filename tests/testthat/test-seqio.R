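test_that("FASTA reading preserves records, wrapping and order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  g <- read_genome_fasta(f)
  expect_equal(g$chrom_id, "c1")
  expect_equal(g$sequence, "ACGT")
  expect_equal(g$length_bp, 4L)

  writeLines(c(">a", "AC", "GT", ">b", "NN"), f)
  g <- read_genome_fasta(f)
  expect_equal(g$chrom_id, c("a", "b"))
  expect_equal(g$sequence[1], "ACGT")

  writeLines(c(">a", "acgt"), f)
  expect_equal(read_genome_fasta(f)$sequence, "ACGT")
})

test_that("FASTA round-trips are lossless", {
  f <- withr::local_tempfile(fileext = ".fa")
  g <- data.frame(chrom_id = c("chrA", "chrB"),
                  sequence = c("ACGTACGTNN", "TTTT"),
                  length_bp = c(10L, 4L), stringsAsFactors = FALSE)
  write_fasta(g, f)
  expect_equal(read_genome_fasta(f), g)

  p <- data.frame(id = c("p1", "p2"), species = c("panda", NA),
                  sequence = c("MKTW", "MAACD"),
                  annotation = c("an OR", NA), stringsAsFactors = FALSE)
  write_fasta(p, f)
  expect_equal(read_protein_fasta(f), p)
})

test_that("malformed and empty FASTA raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_genome_fasta(f), "empty")
  writeLines(c("ACGT", ">a"), f)
  expect_error(read_genome_fasta(f), "line 1")
  writeLines(c("", "ACGT"), f)
  expect_error(read_protein_fasta(f), "line 2")
})

test_that("protein records reject internal stop characters", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "MKT*", ">bad", "MK*T"), f)
  expect_error(read_protein_fasta(f), "bad")
})

test_that("GFF3 round-trip preserves coordinates, class labels, disruptions", {
  models <- data.frame(
    gene_id = c("g1", "g2"), chrom_id = c("chr1", "chr1"),
    strand = c("+", "-"), start = c(100L, 5000L), end = c(1029L, 5900L),
    class_label = c("functional", "pseudogene"),
    disruptions = c("", "premature_stop:5450,frameshift:5600"),
    best_query_id = c("q1", "q2"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  genome <- data.frame(chrom_id = "chr1", sequence = strrep("A", 10000),
                       length_bp = 10000L, stringsAsFactors = FALSE)
  write_gff3(models, f, genome)
  back <- read_gff3(f)
  expect_equal(back[order(back$start), names(models)], models,
               ignore_attr = TRUE)
})

test_that("GFF3 rejects out-of-bounds coordinates and handles empty input", {
  models <- data.frame(gene_id = "g1", chrom_id = "chr1", strand = "+",
                       start = 100L, end = 2000L,
                       class_label = "functional", disruptions = "",
                       best_query_id = "q", stringsAsFactors = FALSE)
  genome <- data.frame(chrom_id = "chr1", sequence = strrep("A", 1000),
                       length_bp = 1000L, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  expect_error(write_gff3(models, f, genome), "bounds")
  write_gff3(models[0, ], f)
  expect_equal(nrow(read_gff3(f)), 0)
  expect_match(readLines(f)[1], "gff-version 3")
})

test_that("run configuration validates thresholds and round-trips as JSON", {
  cfg <- or_config()
  expect_equal(cfg$evalue_threshold, 1e-10)
  expect_equal(cfg$min_functional_aa, 250L)
  expect_equal(cfg$family_identity, 0.40)
  expect_equal(cfg$subfamily_identity, 0.60)
  expect_equal(cfg$cluster_gap_bp, 1000000L)
  expect_error(or_config(family_identity = 0.7, subfamily_identity = 0.6),
               "family_identity")
  expect_error(or_config(evalue_threshold = 0), "evalue")
  expect_error(or_config(min_functional_aa = 0), "min_functional_aa")
  f <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, f)
  expect_equal(read_config(f), cfg)
})

test_that("human OR table reader validates required columns", {
  tab <- synthetic_human_or_table(seed = 3)
  expect_true(all(c("gene", "accession", "odorants", "or_class",
                    "sequence") %in% names(tab)))
  expect_setequal(unique(tab$or_class), c("I", "II"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, c("gene", "accession")], f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_human_or_table(f), "missing column")
})
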