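test_that("synthetic families satisfy the gene-model invariants", {
  fam <- make_family(n_genes = 6, identity = 0.92, seed = 4)
  expect_length(fam, 6L)
  for (g in fam) {
    expect_s3_class(g, "DefensinGene")
    expect_equal(nchar(g$cds) %% 3, 0)
    expect_true(check_frame_and_stop(g$cds)$pass)
    expect_equal(nchar(g$prepro), 92L)
    expect_equal(g$mature_len, 33L)
    # six cysteines at family-conserved offsets
    expect_equal(nchar(g$mature) - nchar(gsub("C", "", g$mature)), 6L)
  }
  offs <- lapply(fam, function(g) gregexpr("C", g$mature)[[1]])
  expect_true(all(vapply(offs, identical, logical(1), offs[[1]])))
})

test_that("families are deterministic per seed and identity is on target", {
  f1 <- make_family(n_genes = 5, identity = 0.95, seed = 7)
  f2 <- make_family(n_genes = 5, identity = 0.95, seed = 7)
  expect_identical(vapply(f1, `[[`, character(1), "cds"),
                   vapply(f2, `[[`, character(1), "cds"))
  id <- family_identity(f1)
  expect_gte(id, 0.93)
  expect_lte(id, 0.97)
  f3 <- make_family(n_genes = 5, identity = 0.95, seed = 8)
  expect_false(identical(vapply(f1, `[[`, character(1), "cds"),
                         vapply(f3, `[[`, character(1), "cds")))
})

test_that("a family FASTA/TSV pair round-trips", {
  fam <- make_family(n_genes = 3, seed = 2)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_family(fam, fa, tsv)
  back <- read_family(fa, tsv)
  expect_identical(vapply(back, `[[`, character(1), "cds"),
                   vapply(fam, `[[`, character(1), "cds"))
  expect_identical(vapply(back, `[[`, integer(1), "mature_start"),
                   vapply(fam, `[[`, integer(1), "mature_start"))
})

test_that("impossibly low identity is rejected", {
  expect_error(make_family(identity = 0.3), "identity")
})

test_that("pool fractions sum to one and respect the configured shares", {
  fam <- make_family(n_genes = 8, seed = 5)
  cs <- enumerate_all(fam)
  pool <- make_pool(fam, cs, seed = 6)
  expect_equal(sum(pool$fraction), 1)
  expect_equal(sum(pool$fraction[pool$role != "background"]), 0.8519,
               tolerance = 1e-12)
  chim <- sum(pool$fraction[pool$role == "chimera"])
  expect_equal(chim / sum(pool$fraction[pool$role != "background"]), 0.0024,
               tolerance = 1e-12)
  # dominant parental share
  par <- pool$fraction[pool$role == "parental"]
  expect_equal(max(par) / sum(pool$fraction[pool$role != "background"]) /
                 (1 - 0.0024), 0.164, tolerance = 1e-9)
})

test_that("a zero chimera fraction yields a purely parental family pool", {
  fam <- make_family(n_genes = 4, seed = 9)
  pool <- make_pool(fam, NULL, chimera_fraction = 0, family_fraction = 1,
                    n_background = 0L, seed = 1)
  expect_setequal(pool$role, "parental")
  expect_equal(sum(pool$fraction), 1)
})

test_that("a positive chimera fraction without chimeras is an error", {
  fam <- make_family(n_genes = 4, seed = 9)
  expect_error(make_pool(fam, NULL, chimera_fraction = 0.01), "empty")
})

test_that("sampled molecule counts land within binomial noise of the target", {
  fam <- make_family(n_genes = 8, seed = 5)
  cs <- enumerate_all(fam)
  pool <- make_pool(fam, cs, family_fraction = 1, n_background = 0L,
                    n_molecules = 1e6, seed = 10)
  chim <- sum(pool$count[pool$role == "chimera"])
  expect_lt(abs(chim - 2400), 3 * sqrt(1e6 * 0.0024 * 0.9976))
  expect_equal(sum(pool$count), 1e6)
})

test_that("error-free reads are exact substrings of their source", {
  fam <- make_family(n_genes = 4, seed = 3)
  pool <- make_pool(fam, NULL, chimera_fraction = 0, family_fraction = 1,
                    n_background = 0L, seed = 2)
  sim <- simulate_reads(pool, n_reads = 300, read_len = 60, error_rate = 0,
                        seed = 5)
  seqs <- setNames(pool$sequence, pool$id)
  for (i in seq_len(300)) {
    src <- seqs[[sim$truth$source_id[i]]]
    expect_identical(unname(sim$reads[i]),
                     substr(src, sim$truth$start[i], sim$truth$start[i] + 59L))
  }
})

test_that("the realised substitution rate matches the configured rate", {
  fam <- make_family(n_genes = 4, seed = 3)
  pool <- make_pool(fam, NULL, chimera_fraction = 0, family_fraction = 1,
                    n_background = 0L, seed = 2)
  n <- 2e4; L <- 70; rate <- 0.001
  sim <- simulate_reads(pool, n_reads = n, read_len = L, error_rate = rate,
                        seed = 6)
  observed <- sum(sim$truth$n_errors) / (n * L)
  expect_lt(abs(observed - rate), 3 * sqrt(rate * (1 - rate) / (n * L)))
  # reads are reproducible per seed
  sim2 <- simulate_reads(pool, n_reads = n, read_len = L, error_rate = rate,
                         seed = 6)
  expect_identical(sim$reads, sim2$reads)
})

test_that("paired mode emits a reverse-complemented mate from the fragment", {
  fam <- make_family(n_genes = 3, seed = 8)
  pool <- make_pool(fam, NULL, chimera_fraction = 0, family_fraction = 1,
                    n_background = 0L, seed = 2)
  sim <- simulate_reads(pool, n_reads = 50, read_len = 60, error_rate = 0,
                        paired = TRUE, fragment_len = 150, seed = 3)
  seqs <- setNames(pool$sequence, pool$id)
  for (i in 1:50) {
    frag <- substr(seqs[[sim$truth$source_id[i]]], sim$truth$start[i],
                   sim$truth$start[i] + 149L)
    expect_identical(unname(sim$reads[i]), substr(frag, 1, 60))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(frag, 91, 150))))
    expect_identical(unname(sim$mate2[i]), rc)
  }
})

test_that("fastq output round-trips and truth counts reconcile", {
  fam <- make_family(n_genes = 3, seed = 8)
  pool <- make_pool(fam, NULL, chimera_fraction = 0, family_fraction = 1,
                    n_background = 0L, seed = 2)
  sim <- simulate_reads(pool, n_reads = 100, read_len = 60, seed = 4)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(unname(as.character(back)), unname(sim$reads))
  expect_true(all(sim$truth$source_id %in% pool$id))
  expect_equal(nrow(sim$truth), 100L)
})
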