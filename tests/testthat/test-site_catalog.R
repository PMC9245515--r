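# small helper to build a hand-written PSM row
psm_row <- function(chain_id, start, end, sequence, mod_string,
                    spectrum_id = paste0("s", start, "_", mod_string)) {
  data.frame(spectrum_id = spectrum_id, chain_id = chain_id, start = start,
             end = end, sequence = sequence, mod_string = mod_string,
             label = peptidoform_label(sequence, mod_string),
             score = 20, n_matched = 10, is_decoy = FALSE, q_value = 0,
             stringsAsFactors = FALSE)
}

# chain with a Gly-Pro-Pro cluster (3-HyP context), an Xaa-P with Ala in
# Yaa (ambiguous context), and a G-X-K lysine
catalog_chain <- function() {
  collagen_chain("chainA", "AAAKGPPGPAGPKGDRAAK",
                 n_propeptide = c(1, 4), c_propeptide = c(17, 19))
}

test_that("hydroxyproline classification follows the positional rule", {
  ch <- catalog_chain()
  chains <- list(chainA = ch)
  # G P(+O) P(+O): Xaa-P is 3-HyP, Yaa-P is 4-HyP
  psms <- psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "2:HyP;3:HyP")
  cat1 <- assign_sites(psms, chains)
  expect_equal(cat1$sites$classification[cat1$sites$position == 6], "HYP3")
  expect_equal(cat1$sites$classification[cat1$sites$position == 7], "HYP4")
  # hydroxylated Xaa-P with Ala in Yaa is ambiguous
  psms2 <- psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "5:HyP")
  cat2 <- assign_sites(psms2, chains)
  expect_equal(cat2$sites$classification[cat2$sites$position == 9],
               "HYP_AMBIGUOUS")
  # without the co-occurring Yaa hydroxylation the Xaa-P is not 3-HyP...
  psms3 <- psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "2:HyP")
  cat3 <- assign_sites(psms3, chains)
  expect_equal(cat3$sites$classification[cat3$sites$position == 6],
               "HYP_AMBIGUOUS")
  # ...unless the relaxed rule accepts Yaa hydroxylation from any PSM
  psms4 <- rbind(psms3, psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "3:HyP"))
  cat4 <- assign_sites(psms4, chains, relaxed_hyp3 = TRUE)
  expect_equal(cat4$sites$classification[cat4$sites$position == 6], "HYP3")
  cat4s <- assign_sites(psms4, chains, relaxed_hyp3 = FALSE)
  expect_equal(cat4s$sites$classification[cat4s$sites$position == 6],
               "HYP_AMBIGUOUS")
})

test_that("lysine sites accumulate states and unmodified support", {
  ch <- catalog_chain()
  chains <- list(chainA = ch)
  psms <- rbind(
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "9:HyK", "sp1"),
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "9:GG-HyK", "sp2"),
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "", "sp3")
  )
  cat <- assign_sites(psms, chains)
  k <- cat$sites[cat$sites$position == 13, ]
  expect_equal(k$classification, "LYS_SITE")
  expect_equal(k$n_HyK, 1L)
  expect_equal(k$n_GGHyK, 1L)
  expect_equal(k$n_unmod, 1L)
  expect_match(k$states, "unmod")
  # decoys and unknown chains are rejected
  bad <- psms
  bad$is_decoy[1] <- TRUE
  expect_error(assign_sites(bad, chains), "decoy")
  bad2 <- psms
  bad2$chain_id <- "nope"
  expect_error(assign_sites(bad2, chains), "unknown chain")
  # no PSMs: empty catalog, zero coverage
  cat0 <- assign_sites(psms[0, ], chains)
  expect_equal(nrow(cat0$sites), 0)
  expect_equal(cat0$coverage$coverage, 0)
})

test_that("catalog merge over PSM unions is idempotent", {
  chains <- list(chainA = catalog_chain())
  a <- psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "2:HyP;3:HyP", "u1")
  b <- psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "9:HyK", "u2")
  merged <- assign_sites(rbind(a, b), chains)
  sep <- rbind(assign_sites(a, chains)$sites, assign_sites(b, chains)$sites)
  expect_setequal(merged$sites$position, sep$position)
  # rerunning on the union changes nothing
  expect_identical(merged$sites, assign_sites(rbind(a, b), chains)$sites)
})

test_that("sequence coverage counts distinct mature positions once", {
  ch <- collagen_chain("cov", strrep("GPKGAAGPR", 13),
                       n_propeptide = c(1, 8), c_propeptide = c(109, 117))
  # mature range 9..108 = 100 residues
  expect_equal(diff(mature_range(ch)) + 1, 100)
  one <- psm_row("cov", 10, 19, substr(chain_sequence(ch), 10, 19), "")
  expect_equal(sequence_coverage(one, ch), 10.0)
  overlap <- rbind(one, psm_row("cov", 15, 24,
                                substr(chain_sequence(ch), 15, 24), ""))
  expect_equal(sequence_coverage(overlap, ch), 15.0)
  tile <- psm_row("cov", 9, 108, substr(chain_sequence(ch), 9, 108), "")
  expect_equal(sequence_coverage(tile, ch), 100)
  # mature interval must be defined
  bare <- collagen_chain("bare", "GPKGAAGPR")
  expect_equal(sequence_coverage(one, bare), 0) # no PSMs for that chain id
  expect_equal(mature_range(bare), c(1L, 9L)) # full chain when unannotated
})

test_that("catalog tallies count microheterogeneity sites in every state", {
  chains <- list(chainA = catalog_chain())
  psms <- rbind(
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "2:HyP;3:HyP", "t1"),
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "9:HyK", "t2"),
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "9:G-HyK", "t3"),
    psm_row("chainA", 5, 16, "GPPGPAGPKGDR", "9:GG-HyK", "t4")
  )
  tal <- tabulate_catalog(assign_sites(psms, chains))
  row <- tal[tal$chain_id == "chainA", ]
  expect_equal(c(row$hyp3, row$hyk, row$ghyk, row$gghyk), c(1, 1, 1, 1))
  tot <- tal[tal$chain_id == "TOTAL", ]
  expect_equal(tot$hyp3 + tot$hyk + tot$ghyk + tot$gghyk, 4)
  # empty catalog tallies to all zeros
  tal0 <- tabulate_catalog(assign_sites(psms[0, ], chains))
  expect_equal(sum(tal0[tal0$chain_id == "TOTAL", -1]), 0)
})

test_that("conserved-site mapping respects alignment gaps and classes", {
  sites_a <- data.frame(chain_id = "a", position = c(5, 10, 20),
                        classification = "HYP3")
  sites_b <- data.frame(chain_id = "b", position = c(5, 10),
                        classification = "HYP3")
  aln <- identity_alignment(25)
  res <- conserved_sites(sites_a, sites_b, aln)
  expect_equal(res$conserved$pos_a, c(5, 10))
  expect_equal(res$specific_a, 20)
  # identical catalogs on identical chains: everything conserved
  res2 <- conserved_sites(sites_a, sites_a, aln)
  expect_equal(nrow(res2$conserved), 3)
  expect_length(res2$specific_a, 0)
  # a site opposite an alignment gap is unmatched
  gap <- identity_alignment(25)
  gap$pairs <- gap$pairs[gap$pairs$qpos != 10, ]
  res3 <- conserved_sites(sites_a, sites_b, gap)
  expect_true(10 %in% res3$specific_a)
  expect_error(conserved_sites(sites_a, sites_b, NULL), "alignment")
})

test_that("fixture conservation split reproduces the published 10 + 14 = 24", {
  split <- col1a1a_conservation_split()
  expect_equal(nrow(split$conserved), 10)
  expect_length(split$specific_a, 14)
  expect_equal(nrow(split$conserved) + length(split$specific_a), 24)
  # the published conserved set
  expect_setequal(split$conserved$pos_a,
                  c(176, 551, 755, 800, 869, 881, 911, 1103, 1106, 1148))
})
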