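simple_index <- function(seqs, k = 21, roles = NULL)
  build_index(data.frame(id = names(seqs), sequence = unname(seqs),
                         role = if (is.null(roles)) "parental" else roles))

test_that("the index covers every k-mer and rejects duplicates", {
  set.seed(1)
  s <- random_dna(21)
  idx <- build_index(c(tx = s), k = 21)
  expect_identical(kmer_hits(idx, s), "tx")
  long <- random_dna(60)
  idx2 <- build_index(c(a = long), k = 21)
  for (p in seq_len(40)) {
    expect_identical(kmer_hits(idx2, substr(long, p, p + 20L)), "a")
  }
  expect_error(build_index(c(a = long, a = long)), "duplicate")
  expect_error(build_index(c(a = "ACGT"), k = 21), "at least k")
})

test_that("a shared block maps its k-mers to both transcripts", {
  set.seed(2)
  block <- random_dna(30)
  t1 <- paste0(random_dna(25), block, random_dna(25))
  t2 <- paste0(random_dna(30), block)
  idx <- simple_index(c(t1 = t1, t2 = t2))
  for (p in 1:10) {
    km <- substr(block, p, p + 20L)
    expect_setequal(kmer_hits(idx, km), c("t1", "t2"))
  }
})

test_that("symmetric reads from two distinct transcripts give ~equal TPM", {
  set.seed(3)
  seqs <- c(a = random_dna(300), b = random_dna(300))
  pool <- data.frame(id = names(seqs), sequence = unname(seqs),
                     role = "parental", fraction = c(0.5, 0.5))
  sim <- simulate_reads(pool, n_reads = 6000, read_len = 70, error_rate = 0,
                        seed = 4)
  q <- quantify(sim$reads, simple_index(seqs), error_rate = 0,
                max_mismatches = 0)
  expect_equal(sum(q$table$tpm), 1e6, tolerance = 1e-6)
  expect_equal(q$table$tpm[1], 5e5, tolerance = 0.05)
})

test_that("reads from one transcript only give it the full million", {
  set.seed(5)
  seqs <- c(a = random_dna(300), b = random_dna(300))
  pool <- data.frame(id = "a", sequence = seqs[["a"]], role = "parental",
                     fraction = 1)
  sim <- simulate_reads(pool, n_reads = 1000, read_len = 70, error_rate = 0,
                        seed = 6)
  q <- quantify(sim$reads, simple_index(seqs), error_rate = 0)
  expect_equal(setNames(q$table$tpm, q$table$id), c(a = 1e6, b = 0))
})

test_that("TPM sums to one million and the EM is deterministic", {
  fam <- family_small(5, seed = 23)
  cs <- enumerate_all(fam)
  pool <- make_pool(fam, cs, seed = 24)
  sim <- simulate_reads(pool, n_reads = 3e4, read_len = 70,
                        error_rate = 0.001, seed = 25)
  idx <- build_index(data.frame(id = pool$id, sequence = pool$sequence,
                                role = pool$role))
  q1 <- quantify(sim$reads, idx)
  q2 <- quantify(sim$reads, idx)
  expect_identical(q1$table, q2$table)
  expect_equal(sum(q1$table$tpm, na.rm = TRUE), 1e6, tolerance = 1e-6)
})

test_that("decoys absorb reads but are excluded from TPM", {
  set.seed(7)
  shared <- random_dna(150)
  seqs <- c(real = paste0(shared, random_dna(100)),
            trap = paste0(shared, random_dna(100)))
  pool <- data.frame(id = names(seqs), sequence = unname(seqs),
                     role = "parental", fraction = c(0.5, 0.5))
  sim <- simulate_reads(pool, n_reads = 4000, read_len = 70, error_rate = 0,
                        seed = 8)
  q <- quantify(sim$reads, simple_index(seqs, roles = c("parental", "decoy")),
                error_rate = 0)
  tab <- q$table
  expect_true(is.na(tab$tpm[tab$id == "trap"]))
  expect_equal(tab$tpm[tab$id == "real"], 1e6)
  expect_gt(tab$count[tab$id == "trap"], 0)
})

test_that("adding chimeras to the index never raises a parental's TPM", {
  fam <- family_small(6, seed = 29)
  cs <- enumerate_all(fam)
  pool <- make_pool(fam, cs, seed = 30)
  sim <- simulate_reads(pool, n_reads = 4e4, read_len = 70,
                        error_rate = 0.001, seed = 31)
  par_only <- pool[pool$role == "parental", ]
  q_par <- quantify(sim$reads,
                    build_index(data.frame(id = par_only$id,
                                           sequence = par_only$sequence,
                                           role = "parental")))
  q_all <- quantify(sim$reads,
                    build_index(data.frame(id = pool$id,
                                           sequence = pool$sequence,
                                           role = pool$role)))
  t_par <- setNames(q_par$table$tpm, q_par$table$id)
  t_all <- setNames(q_all$table$tpm, q_all$table$id)
  ids <- names(t_par)
  expect_true(all(t_all[ids] <= t_par[ids] * (1 + 1e-8)))
})

test_that("an empty read set warns and returns zero counts", {
  set.seed(9)
  idx <- simple_index(c(a = random_dna(100)))
  expect_warning(q <- quantify(character(0), idx), "empty")
  expect_equal(q$n_reads, 0L)
  expect_equal(q$table$count, 0)
})

mutate_at <- function(r, p) {
  cur <- substr(r, p, p)
  substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  r
}

test_that("split support recovers planted breakpoints exactly", {
  set.seed(10)
  hits <- 0L
  for (i in 1:25) {
    left <- random_dna(120); right <- random_dna(120)
    off <- sample(0:50, 1)
    b <- 31L
    read <- paste0(substr(left, off + 1, off + b),
                   substr(right, off + b + 1, off + 60))
    read <- mutate_at(mutate_at(read, sample(1:29, 1)), sample(34:60, 1))
    sp <- split_read_support(read, left, right)
    o <- oracle_best_split(read, left, right, sp$offset_left, sp$offset_right)
    # always identical to the brute-force oracle (same smallest-b tie-break)
    expect_equal(sp$breakpoint_in_read, o$b)
    expect_equal(sp$mismatches_left, o$ml)
    expect_equal(sp$mismatches_right, o$mr)
    expect_equal(sp$mismatches_left + sp$mismatches_right, 2L)
    # the planted breakpoint is recovered exactly whenever the two parents
    # disagree on both junction-flanking bases (no tie ambiguity)
    flank_differs <-
      substr(left, off + 31, off + 31) != substr(right, off + 31, off + 31) &&
      substr(left, off + 32, off + 32) != substr(right, off + 32, off + 32)
    if (flank_differs) {
      expect_equal(sp$breakpoint_in_read, 31L)
      hits <- hits + 1L
    }
  }
  expect_gt(hits, 10L)
})

test_that("a read identical to the left parent splits at the read end", {
  set.seed(12)
  left <- random_dna(150)
  # homologous right parent differing inside the read window and at its last
  # base, so the end split is the unique minimum
  right <- mutate_at(mutate_at(left, 70), 100)
  read <- substr(left, 41, 100)
  sp <- split_read_support(read, left, right)
  expect_equal(sp$breakpoint_in_read, 60L)
  expect_equal(sp$mismatches_left, 0L)
  expect_equal(sp$mismatches_right, 0L)
  expect_true(sp$supported)
})

test_that("hopeless anchoring is reported as unsupported", {
  set.seed(13)
  sp <- split_read_support(random_dna(60), random_dna(80), random_dna(80))
  expect_false(sp$supported)
})

test_that("error-free parental pools give zero chimera split-read calls", {
  fam <- family_small(6, seed = 35)
  pool <- make_pool(fam, NULL, chimera_fraction = 0, family_fraction = 1,
                    n_background = 0L, seed = 36)
  sim <- simulate_reads(pool, n_reads = 2e4, read_len = 70, error_rate = 0,
                        seed = 37)
  calls <- screen_split_reads(sim$reads,
                              setNames(pool$sequence, pool$id),
                              max_mismatches = 0)
  expect_equal(nrow(calls), 0L)
})

test_that("spiked chimeric reads do produce supported split calls", {
  fam <- family_small(4, seed = 39)
  cs <- enumerate_all(fam)
  pool <- make_pool(fam, cs, chimera_fraction = 0.2, family_fraction = 1,
                    n_background = 0L, n_active_chimeras = 3L, seed = 40)
  sim <- simulate_reads(pool, n_reads = 3000, read_len = 70, error_rate = 0,
                        seed = 41)
  parentals <- pool[pool$role == "parental", ]
  calls <- screen_split_reads(sim$reads,
                              setNames(parentals$sequence, parentals$id),
                              max_mismatches = 0)
  expect_gt(nrow(calls), 0L)
  # calls coincide with reads whose true source is chimeric
  truth_chim <- sim$truth$read_id[sim$truth$role == "chimera"]
  expect_true(all(calls$read_id %in% truth_chim))
})

test_that("occurrence summary reproduces hand-computed percentages", {
  set.seed(14)
  mat <- matrix(rbinom(40, 1, 0.4), nrow = 10, ncol = 4)
  mat[1, ] <- 0
  s <- occurrence_summary(mat)
  det <- rowSums(mat > 0)
  expect_equal(s$never, sum(det == 0))
  expect_equal(s$never_pct_total, round(100 * sum(det == 0) / 10, 2))
  expect_equal(s$le_lo, sum(det <= floor(4 / 3)))
  expect_equal(s$ge_hi, sum(det >= ceiling(8 / 3)))
  expect_equal(s$in_band_pct_detected,
               round(100 * sum(det >= 1 & det <= 50) / sum(det > 0), 2))
  expect_error(occurrence_summary(mat[, 0]), "zero")
  z <- occurrence_summary(matrix(0, 5, 3))
  expect_equal(z$never_pct_total, 100)
})

test_that("donor/acceptor totals are additive and match a summation oracle", {
  quant <- data.frame(id = c("c1", "c2", "c3"),
                      tpm = c(100.5, 60, 86))
  map <- data.frame(id = c("c1", "c2", "c3"),
                    donor_id = c("Defa24", "Defa24", "Defa3"),
                    acceptor_id = c("Defa3", "Defa3", "Defa24"))
  tot <- donor_acceptor_totals(quant, map)
  d24 <- tot[tot$parent == "Defa24", ]
  expect_equal(d24$donor_tpm, 160.5)
  expect_equal(d24$acceptor_tpm, 86)
  expect_equal(d24$total_tpm, 246.5)
  expect_equal(attr(tot, "grand_total"), 246.5)
  expect_equal(tot$total_tpm, tot$donor_tpm + tot$acceptor_tpm)
  expect_error(donor_acceptor_totals(quant, map[-1, ]), "missing")
})

test_that("zero chimeric TPM gives zero totals", {
  quant <- data.frame(id = c("c1", "c2"), tpm = c(0, 0))
  map <- data.frame(id = c("c1", "c2"), donor_id = c("a", "b"),
                    acceptor_id = c("b", "a"))
  tot <- donor_acceptor_totals(quant, map)
  expect_true(all(tot$total_tpm == 0))
})
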