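test_that("sequence utilities normalize, round-trip and select isoforms", {
  expect_identical(rna_normalize("acgt"), "ACGU")
  expect_error(rna_normalize("ACGN"), "non-RNA")
  expect_identical(revcomp_rna("AAGC"), "GCUU")

  set.seed(2)
  seqs <- setNames(random_rna(3, c(120, 80, 150)), c("tA", "tB", "tC"))
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  back <- read_fasta(p)
  expect_identical(back, seqs)

  gm <- data.frame(transcript_id = c("tA", "tB", "tC"),
                   gene_id = c("G1", "G1", "G2"), stringsAsFactors = FALSE)
  sel <- select_longest_utr(seqs, gm)
  expect_identical(names(sel), c("G1", "G2"))
  expect_identical(unname(nchar(sel)), c(120L, 150L))

  # equal-length tie resolves to the lexicographically smallest id
  ties <- setNames(random_rna(2, 110), c("tZ", "tY"))
  gm2 <- data.frame(transcript_id = c("tZ", "tY"), gene_id = "G3",
                    stringsAsFactors = FALSE)
  sel2 <- select_longest_utr(ties, gm2)
  expect_identical(unname(sel2["G3"]), unname(ties[["tY"]]))

  # genes whose longest UTR is short are dropped with a count
  shorties <- setNames(random_rna(2, c(80, 90)), c("u1", "u2"))
  gm3 <- data.frame(transcript_id = c("u1", "u2"), gene_id = "G4",
                    stringsAsFactors = FALSE)
  expect_message(sel3 <- select_longest_utr(shorties, gm3), "dropped")
  expect_identical(length(sel3), 0L)
})

test_that("duplex energies behave physically", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  # a window with no pairing potential scores zero
  expect_identical(duplex_energy(strrep("A", 25), strrep("A", 22)), 0)
  # a perfect complement is far below every one of 100 shuffles
  site <- revcomp_rna(mir)
  e_match <- duplex_energy(site, mir)
  expect_lt(e_match, -25)
  set.seed(10)
  shuffles <- vapply(1:100, function(i)
    paste(sample(strsplit(site, "")[[1]]), collapse = ""), character(1))
  e_shuf <- duplex_energy(shuffles, mir)
  expect_true(all(e_match < e_shuf))
  expect_true(all(e_shuf <= 0))
  # invariant to the identity of the unpairable linker
  expect_identical(duplex_energy(site, mir, linker = "XXXXXXXX"),
                   duplex_energy(site, mir, linker = "NNNNNNNN"))
  expect_error(duplex_energy(site, mir, linker = "AAAAAAAA"), "unpairable")
})

test_that("the sliding scan counts windows and matches a direct rescan", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  set.seed(4)
  utr <- random_rna(1, 100)
  w <- energy_walk(mir, utr)
  expect_identical(w$n_windows, 16L)   # floor((100-25)/5)+1

  # independent rescan over the same starts
  starts <- seq(1, 76, by = 5)
  direct <- vapply(starts, function(s)
    duplex_energy(substr(utr, s, s + 24), mir), numeric(1))
  expect_equal(w$min_energy, min(direct))
  expect_equal(w$window_start, starts[which.min(direct)])

  # a finer step can only find an equal-or-lower minimum
  w1 <- energy_walk(mir, utr, step = 1)
  expect_lte(w1$min_energy, w$min_energy)
  expect_error(energy_walk(mir, random_rna(1, 20)), "shorter")
})

test_that("a planted perfect site is localized by the scan", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  set.seed(5)
  utr <- random_rna(1, 150)
  site <- revcomp_rna(mir)
  substr(utr, 41, 41 + nchar(site) - 1) <- site
  w <- energy_walk(mir, utr)
  expect_lte(abs(w$window_start - 41), 5)
})

test_that("randomizations preserve the right invariants", {
  pairs <- data.frame(mirna_id = sprintf("m%d", 1:6),
                      target_id = sprintf("u%d", 1:6),
                      stringsAsFactors = FALSE)
  r1 <- randomize_labels(pairs, seed = 3)
  expect_setequal(r1$target_id, pairs$target_id)
  expect_identical(r1$mirna_id, pairs$mirna_id)
  expect_identical(randomize_labels(pairs, seed = 3), r1)
  expect_error(randomize_labels(pairs[1, ], seed = 1), ">= 2")

  set.seed(1)
  utrs <- setNames(random_rna(6, 120), pairs$target_id)
  pool <- setNames(random_rna(3, 120), sprintf("alt%d", 1:3))
  r2 <- randomize_sequences(pairs, utrs, pool, seed = 4)
  expect_identical(nrow(r2$pairs), 6L)
  expect_identical(r2$pairs$target_id[1:3] %in% names(pool), rep(TRUE, 3))
  expect_true(all(grepl("synthetic_random", r2$pairs$target_id[4:6])))
  expect_identical(randomize_sequences(pairs, utrs, pool, seed = 4)$pairs,
                   r2$pairs)
  one <- randomize_sequences(pairs[1, ], utrs[1], pool[1], seed = 1)
  expect_identical(one$pairs$target_id, names(pool)[1])
})

test_that("Welch statistics match the closed form", {
  w <- welch_ttest(c(1, 2, 3), c(2, 3, 4))
  # closed form: t = (1-...)/sqrt(s2x/3 + s2y/3), both variances 1
  t_ref <- (2 - 3) / sqrt(1 / 3 + 1 / 3)
  df_ref <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(w$t, t_ref, tolerance = 1e-12)
  expect_equal(w$df, df_ref, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-12)

  same <- welch_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sw <- welch_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p, w$p)
  expect_error(welch_ttest(c(1, 1), c(1, 1)), "zero variance")
})

test_that("the comparison grid is complete and sane on identical groups", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(10, 11, 12, 13))
  grid <- compare_energy_distributions(g)
  expect_identical(nrow(grid), 3L)
  ab <- grid[grid$group1 == "a" & grid$group2 == "b", ]
  expect_equal(ab$p, 1)
  ac <- grid[grid$group1 == "a" & grid$group2 == "c", ]
  expect_lt(ac$p, 0.001)
})

test_that("planted sites separate matched pairs from both nulls", {
  set.seed(60)
  mirs <- setNames(random_rna(20, 22), sprintf("mir%d", 1:20))
  ms <- make_sequences(40, c(120, 200), mirs, planted_fraction = 1,
                       seed = 6)
  matched <- energy_walk_pairs(ms$pairs, ms$mirnas, ms$utrs)
  lab <- randomize_labels(ms$pairs, seed = 7)
  permuted <- energy_walk_pairs(lab, ms$mirnas, ms$utrs)
  rs <- randomize_sequences(ms$pairs, ms$utrs,
                            setNames(random_rna(40, 150),
                                     sprintf("alt%d", 1:40)), seed = 8)
  substituted <- energy_walk_pairs(rs$pairs, ms$mirnas, rs$utrs)

  grid <- compare_energy_distributions(list(
    matched = matched$min_energy,
    label_permuted = permuted$min_energy,
    sequence_randomized = substituted$min_energy))
  p_ml <- grid$p[grid$group1 == "matched" & grid$group2 == "label_permuted"]
  p_ms <- grid$p[grid$group1 == "matched" &
                   grid$group2 == "sequence_randomized"]
  expect_lt(p_ml, 0.01)
  expect_lt(p_ms, 0.01)
  expect_lt(mean(matched$min_energy), mean(permuted$min_energy))
  expect_lt(mean(matched$min_energy), mean(substituted$min_energy))
})

test_that("internal and external folding backends rank pairs alike", {
  skip_if(Sys.which("RNAduplex") == "", "ViennaRNA not on PATH")
  set.seed(9)
  mir <- random_rna(1, 22)
  wins <- random_rna(200, 25)
  e_int <- duplex_energy(wins, mir)
  e_ext <- duplex_energy(wins, mir, backend = "rnaduplex")
  expect_gte(cor(e_int, e_ext, method = "spearman"), 0.8)
})
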