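# two tiny hand-built genes: exon1 encodes M + filler, exon2 encodes the rest
# of a 12-aa protein whose last 8 aa form the "mature" region with 2 cysteines
toy_gene <- function(id, exon2_codons) {
  exon1 <- "ATGGCT"                      # M A
  exon2 <- paste(exon2_codons, collapse = "")
  defensin_gene(id, exon1, exon2, signal_len = 1L, mature_len = 8L,
                mature_start = 3L, n_cys = 2L)
}

test_that("frame and stop checks classify canonical cases", {
  expect_true(check_frame_and_stop("ATGTGTTGA")$pass)
  res <- check_frame_and_stop("ATGTGATGTTGA")
  expect_false(res$pass)
  expect_equal(res$reason, "premature_stop")
  res <- check_frame_and_stop("ATGTG")
  expect_false(res$pass)
  expect_equal(res$reason, "frameshift")
  expect_false(check_frame_and_stop("ATGTGT")$pass)  # no stop
  expect_error(check_frame_and_stop("ATGNNN"), "non-ACGT")
})

test_that("cysteine check distinguishes count from parental-pattern mode", {
  expect_true(check_cysteine_structure("ACCAACCB", n_cys = 4L))
  expect_false(check_cysteine_structure("ACCAACBB", n_cys = 4L))
  # same count, shifted offsets: passes count mode, fails pattern mode
  parental <- list(c(2L, 5L))
  expect_true(check_cysteine_structure("ACAACAAA", mode = "count6",
                                       parental_offsets = parental, n_cys = 2L))
  expect_false(check_cysteine_structure("ACAAACAA", mode = "parental_pattern",
                                        parental_offsets = parental, n_cys = 2L))
  expect_true(check_cysteine_structure("ACAACAAA", mode = "parental_pattern",
                                       parental_offsets = parental, n_cys = 2L))
})

test_that("a self-pair yields no chimeras", {
  g <- family_small(2)[[1]]
  expect_equal(nrow(generate_pair_chimeras(g, g)), 0L)
})

test_that("parents differing at a single codon give no distinct chimeras", {
  # every crossover product equals one parent or the other
  base <- c("TGT", "AAA", "GGT", "TGC", "CCA", "TTG", "GAA", "CAT", "AAG", "TAA")
  alt <- base; alt[5] <- "CGA"
  g1 <- toy_gene("g1", base)
  g2 <- toy_gene("g2", alt)
  expect_equal(nrow(generate_pair_chimeras(g1, g2)), 0L)
  expect_equal(nrow(generate_pair_chimeras(g2, g1)), 0L)
  expect_equal(nrow(enumerate_all(list(g1, g2))$members), 0L)
})

test_that("identical parents give an empty chimera set", {
  base <- c("TGT", "AAA", "GGT", "TGC", "CCA", "TTG", "GAA", "CAT", "AAG", "TAA")
  g1 <- toy_gene("g1", base)
  g2 <- toy_gene("g2", base)
  expect_equal(nrow(enumerate_all(list(g1, g2))$members), 0L)
})

test_that("two separated difference blocks match the exhaustive oracle", {
  base <- c("TGT", "AAA", "GGT", "TGC", "CCA", "TTG", "GAA", "CAT", "AAG", "TAA")
  alt <- base; alt[2] <- "CGA"; alt[7] <- "GTA"
  g1 <- toy_gene("g1", base)
  g2 <- toy_gene("g2", alt)
  cs <- enumerate_all(list(g1, g2))
  oracle <- oracle_enumerate(list(g1, g2))
  expect_setequal(cs$members$cds, oracle)
  expect_gt(nrow(cs$members), 0L)
})

test_that("enumeration equals the brute-force oracle on random families", {
  # small families, short exon 2, many seeds
  for (seed in 1:25) {
    fam <- make_family(n_genes = sample(2:5, 1), identity = 0.88,
                       prepro_len = 30L, signal_len = 5L, mature_len = 12L,
                       n_cys = 3L, exon1_frac = 0.4, seed = seed)
    cs <- enumerate_all(fam)
    oracle <- oracle_enumerate(fam)
    expect_setequal(cs$members$cds, oracle)
  }
})

test_that("no member equals any parental at nucleotide or protein level", {
  fam <- family_small(4, seed = 3)
  cs <- enumerate_all(fam)
  par_nt <- vapply(fam, `[[`, character(1), "cds")
  par_aa <- vapply(fam, `[[`, character(1), "prepro")
  expect_false(any(cs$members$cds %in% par_nt))
  expect_false(any(cs$members$protein %in% par_aa))
  expect_false(anyDuplicated(cs$members$cds) > 0)
})

test_that("every member satisfies the chimeric-transcript invariants", {
  fam <- family_small(3, seed = 5)
  cs <- enumerate_all(fam)
  byid <- setNames(fam, vapply(fam, `[[`, character(1), "gene_id"))
  for (i in seq_len(nrow(cs$members))) {
    m <- cs$members[i, ]
    d <- byid[[m$donor_id]]; a <- byid[[m$acceptor_id]]
    expect_identical(m$cds, paste0(d$exon1_cds,
                                   substr(d$exon2_cds, 1, m$breakpoint),
                                   substr(a$exon2_cds, m$breakpoint + 1,
                                          nchar(a$exon2_cds))))
    expect_equal(nchar(m$cds) %% 3, 0)
    chk <- check_frame_and_stop(m$cds)
    expect_true(chk$pass)
  }
})

test_that("re-enumerating adds nothing (dedup idempotence) and member count is
           monotone in the parental set", {
  fam <- family_small(4, seed = 9)
  cs_all <- enumerate_all(fam)
  cs_sub <- enumerate_all(fam[1:3])
  expect_gte(nrow(cs_all$members), nrow(cs_sub$members))
  # idempotence at the set level: members of the subset run are reproduced
  expect_true(all(cs_sub$members$cds %in% cs_all$members$cds))
  again <- enumerate_all(fam)
  expect_identical(again$members$cds, cs_all$members$cds)
})

test_that("donor/acceptor relabelling symmetry holds for equal exon-2 lengths", {
  fam <- family_small(3, seed = 13)
  cs <- enumerate_all(fam)
  rev_cs <- enumerate_all(rev(fam))
  expect_setequal(cs$members$cds, rev_cs$members$cds)
})

test_that("frameshifted pairs produce an empty list, not an error", {
  base <- c("TGT", "AAA", "GGT", "TGC", "CCA", "TTG", "GAA", "CAT", "AAG", "TAA")
  g1 <- toy_gene("g1", base)
  # acceptor exon2 one base longer: every product is out of frame
  g2 <- g1
  g2$gene_id <- "g2"
  g2$exon2_cds <- paste0("A", g1$exon2_cds)
  out <- generate_pair_chimeras(g1, g2)
  expect_equal(nrow(out), 0L)
})

test_that("rejection ledger accounts for every candidate", {
  fam <- family_small(3, seed = 21)
  cs <- enumerate_all(fam)
  expect_equal(cs$stats[["generated"]],
               nrow(cs$members) + nrow(cs$rejected))
  exon2 <- vapply(fam, function(g) nchar(g$exon2_cds), integer(1))
  expect_equal(cs$stats[["generated"]],
               sum(outer(exon2, exon2, function(a, b) pmin(a, b) - 1L)))
})

test_that("junction position converts nucleotide breakpoints to aa", {
  # exon1 145 nt + breakpoint 20 -> 165 nt -> residue 55
  j <- junction_position(145L, 20L, mature_start = 60L)
  expect_equal(j$prepro_aa, 55L)
  expect_equal(j$mature_aa, -4L)
  j2 <- junction_position(144L, 60L, mature_start = 60L)
  expect_equal(j2$prepro_aa, 68L)
  expect_equal(j2$mature_aa, 9L)
})

test_that("chimera sets round-trip through FASTA output", {
  fam <- family_small(3, seed = 2)
  cs <- enumerate_all(fam)
  nt <- tempfile(fileext = ".fasta")
  aa <- tempfile(fileext = ".faa")
  write_chimera_set(cs, nt, aa)
  seqs <- Biostrings::readDNAStringSet(nt)
  expect_equal(length(seqs), nrow(cs$members))
  expect_equal(unname(as.character(seqs)), cs$members$cds)
})
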